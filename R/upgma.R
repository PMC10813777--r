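#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering of a distance matrix with group-average
#' linkage, used to describe compositional similarity between samples or
#' groups. Merges are deterministic: among tied candidate pairs the one
#' whose lexicographically smallest member id sorts first is merged. The
#' result is an ultrametric tree; leaf branch lengths are merge height / 2,
#' serialized as Newick.
#'
#' @param dm a `dist_matrix`.
#' @return An object of class `upgma_tree`: `merges` (data.frame of merge
#'   heights and member sets), `newick` (string with branch lengths),
#'   `labels`.
#' @export
hclust_average <- function(dm) {
  d <- as_dist_matrix(dm)
  labels <- rownames(d)
  n <- length(labels)
  if (n < 2L) stop_("need >= 2 samples")
  # active clusters: member index sets, sizes, newick fragments, heights
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  frags <- labels
  heights <- rep(0, n)
  key <- labels            # lexicographically smallest member id
  cur <- d
  merge_log <- list()
  while (length(members) > 1L) {
    m <- length(members)
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        dij <- cur[i, j]
        if (dij < best_d - 1e-12) {
          best <- c(i, j); best_d <- dij
        } else if (abs(dij - best_d) <= 1e-12) {
          # tie-break on sorted pair of smallest member ids
          cand <- sort(c(key[i], key[j]))
          inc <- sort(c(key[best[1L]], key[best[2L]]))
          if (cand[1L] < inc[1L] || (cand[1L] == inc[1L] && cand[2L] < inc[2L])) {
            best <- c(i, j); best_d <- dij
          }
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    h <- best_d
    new_frag <- sprintf("(%s:%s,%s:%s)",
                        frags[i], format_full(h / 2 - heights[i]),
                        frags[j], format_full(h / 2 - heights[j]))
    merge_log[[length(merge_log) + 1L]] <- data.frame(
      height = h,
      members = paste(sort(labels[c(members[[i]], members[[j]])]), collapse = ","),
      stringsAsFactors = FALSE)
    # group-average update against every other cluster
    new_row <- (sizes[i] * cur[i, ] + sizes[j] * cur[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(m), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], new_row[keep]),
                 c(new_row[keep], 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    frags <- c(frags[keep], new_frag)
    heights <- c(heights[keep], h / 2)
    key <- c(key[keep], min(key[i], key[j]))
  }
  structure(list(
    merges = do.call(rbind, merge_log),
    newick = paste0(frags[1L], ";"),
    labels = labels
  ), class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree over %d samples; top merge height %.4f\n",
              length(x$labels), max(x$merges$height)))
  invisible(x)
}

#' Write a tree to a Newick file
#' @param tree an `upgma_tree`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  write_tsv_lines(tree$newick, path)
}
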