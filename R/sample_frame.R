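GROUP_LEVELS <- c("C", "N", "T", "M")
LIFESTYLE_LEVELS <- c("PA", "FL")
NUTRIENT_COLS <- c("NH4N", "NO2N", "NO3N", "PO4P")
BIOMASS_COLS <- c("n_oculata", "t_weissflogii")

#' Sample metadata frames
#'
#' A sample frame holds the experimental design factors of each sample --
#' treatment group (C control, N *N. oculata*, T *T. weissflogii*, M mixed),
#' sampling day, tank replicate and bacterial lifestyle (PA
#' particle-attached, FL free-living) -- plus nutrient concentrations (mg/L)
#' and microalgal biomass as numeric covariates.
#'
#' @param df data.frame with at least `sample_id`, `group`, `time`,
#'   `replicate`, `lifestyle`. Extra columns are carried through as
#'   covariates.
#' @return A validated data.frame of class `sample_frame`.
#' @export
sample_frame <- function(df) {
  required <- c("sample_id", "group", "time", "replicate", "lifestyle")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_("missing required column(s): %s", paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop_("duplicate sample_id(s): %s",
          paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$group <- as.character(df$group)
  bad <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad))
    stop_("group value(s) outside {C,N,T,M}: %s", paste(bad, collapse = ", "))
  df$lifestyle <- as.character(df$lifestyle)
  bad <- setdiff(unique(df$lifestyle), LIFESTYLE_LEVELS)
  if (length(bad))
    stop_("lifestyle value(s) outside {PA,FL}: %s", paste(bad, collapse = ", "))
  df$time <- as.integer(df$time)
  df$replicate <- as.integer(df$replicate)
  if (anyNA(df$time) || anyNA(df$replicate))
    stop_("time and replicate must be integral")
  class(df) <- c("sample_frame", "data.frame")
  df
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `group`, `time`, `replicate`,
#'   `lifestyle`; nutrient, biomass and other covariate columns optional.
#' @return A [sample_frame()].
#' @export
read_sample_frame <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop_("no data rows in '%s'", path)
  sample_frame(df)
}

#' Write sample metadata to TSV
#' @param frame a [sample_frame()].
#' @param path output path.
#' @export
write_sample_frame <- function(frame, path) {
  write_tsv_df(as.data.frame(frame), path)
}

# Align a metadata frame to the columns of a count table; every sample must
# appear exactly once.
align_frame <- function(table, frame) {
  m <- as_count_matrix(table)
  idx <- match(colnames(m), frame$sample_id)
  if (anyNA(idx))
    stop_("sample(s) missing from metadata: %s",
          paste(colnames(m)[is.na(idx)], collapse = ", "))
  frame[idx, , drop = FALSE]
}

#' Derive nutrient-change covariates
#'
#' Adds, for each nutrient column present, a `<nutrient>_change` column: the
#' concentration minus the day-0 concentration of the same tank (group x
#' replicate, and lifestyle when present, since both lifestyle fractions come
#' from one tank). The subtraction direction is a stated convention and can
#' be flipped.
#'
#' @param frame a [sample_frame()] containing day-0 rows for every tank.
#' @param columns covariate columns to difference; defaults to the nutrient
#'   columns present.
#' @param sign `"final_minus_initial"` (default) or `"initial_minus_final"`.
#' @return The frame with `_change` columns appended; day-0 rows get 0.
#' @export
nutrient_change <- function(frame,
                            columns = intersect(NUTRIENT_COLS, names(frame)),
                            sign = c("final_minus_initial", "initial_minus_final")) {
  sign <- match.arg(sign)
  if (!length(columns)) stop_("no nutrient columns to difference")
  missing_cols <- setdiff(columns, names(frame))
  if (length(missing_cols))
    stop_("column(s) not in frame: %s", paste(missing_cols, collapse = ", "))
  keys <- c("group", "replicate", intersect("lifestyle", names(frame)))
  key <- interaction(frame[keys], drop = TRUE, lex.order = TRUE)
  for (col in columns) {
    baseline <- tapply(ifelse(frame$time == 0L, frame[[col]], NA_real_),
                       key, function(v) {
                         v <- v[!is.na(v)]
                         if (!length(v)) NA_real_ else v[1L]
                       })
    b <- as.numeric(baseline[as.character(key)])
    no_base <- is.na(b) & !is.na(frame[[col]])
    if (any(no_base))
      stop_("missing day-0 baseline of '%s' for tank(s): %s", col,
            paste(unique(as.character(key)[no_base]), collapse = ", "))
    delta <- frame[[col]] - b
    if (sign == "initial_minus_final") delta <- -delta
    frame[[paste0(col, "_change")]] <- delta
  }
  frame
}
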