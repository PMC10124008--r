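# internal helpers shared across modules

# strict ">50%"-style majority: votes must strictly exceed fraction * n
strict_majority <- function(votes, n_total, fraction) {
  votes > fraction * n_total
}

# Canonical factor-name form: trimmed, case-folded, en/em dashes unified to
# "-". Used only for matching user-supplied names against configured ones;
# the original spelling is kept for display.
normalize_factor_name <- function(x) {
  x <- gsub("–|—", "-", x)
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

# Split a samples-x-features tibble into its id column and a numeric matrix.
# First column (or `id_col`) holds sample ids; all remaining columns must be
# numeric.
df_to_matrix <- function(data, id_col = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(id_col)) id_col <- names(data)[1]
  if (!id_col %in% names(data)) {
    abort(paste0("id column '", id_col, "' not found"))
  }
  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  rest <- data[setdiff(names(data), id_col)]
  bad <- names(rest)[!vapply(rest, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("non-numeric columns: ", paste(bad, collapse = ", ")))
  }
  m <- as.matrix(rest)
  rownames(m) <- ids
  m
}

matrix_to_df <- function(m, id_col = "sample_id") {
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, !!id_col := rownames(m), .before = 1)
  out
}

# align two sample-id-keyed tibbles; error on mismatch
check_aligned <- function(ids_x, ids_y, what = c("features", "panel")) {
  if (length(ids_x) != length(ids_y) || !all(ids_x == ids_y)) {
    miss <- union(setdiff(ids_x, ids_y), setdiff(ids_y, ids_x))
    abort(paste0("sample ids of ", what[1], " and ", what[2],
                 " are not aligned",
                 if (length(miss) > 0)
                   paste0("; unmatched: ", paste(head(miss, 5), collapse = ", "))
                 else ""))
  }
  invisible(TRUE)
}
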