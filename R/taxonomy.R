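TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")
UNASSIGNED <- "Unassigned"

#' Taxonomy tables
#'
#' Ranked lineages per ZOTU (domain..genus). The family rank is mandatory
#' because partition summaries are reported at the family level; missing
#' ranks are encoded by the explicit sentinel `"Unassigned"`, never by empty
#' strings.
#'
#' @param df data.frame with `zotu_id` plus rank columns.
#' @return data.frame of class `taxonomy_table`, one row per ZOTU.
#' @export
taxonomy_table <- function(df) {
  if (!"zotu_id" %in% names(df)) stop_("missing required column: zotu_id")
  if (!"family" %in% names(df)) stop_("missing required column: family")
  df$zotu_id <- as.character(df$zotu_id)
  if (anyDuplicated(df$zotu_id))
    stop_("duplicate zotu_id(s): %s",
          paste(unique(df$zotu_id[duplicated(df$zotu_id)]), collapse = ", "))
  for (r in intersect(TAXONOMY_RANKS, names(df))) {
    v <- as.character(df[[r]])
    v[is.na(v) | !nzchar(v)] <- UNASSIGNED
    df[[r]] <- v
  }
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' Read a taxonomy table from TSV
#' @param path TSV with columns `zotu_id` and rank columns domain..genus.
#' @return A [taxonomy_table()].
#' @export
read_taxonomy_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop_("no data rows in '%s'", path)
  taxonomy_table(df)
}

#' Write a taxonomy table to TSV
#' @param taxonomy a [taxonomy_table()].
#' @param path output path.
#' @export
write_taxonomy_table <- function(taxonomy, path) {
  write_tsv_df(as.data.frame(taxonomy), path)
}
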