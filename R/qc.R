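#' Parse a prophage prediction table
#'
#' Reads a tab-delimited prediction table (CheckV-style columns) into a
#' validated data.frame of prophage records. Coordinates are 1-based
#' inclusive on the contig.
#'
#' @param table Path to a tab-delimited file, or a data.frame.
#' @return A data.frame with columns prophage_id, genome_id, contig_id,
#'   contig_length, start, end, completeness.
#' @export
parse_predictions <- function(table) {
  df <- if (is.character(table) && length(table) == 1L) {
    utils::read.delim(table, stringsAsFactors = FALSE, check.names = FALSE)
  } else if (is.data.frame(table)) {
    table
  } else {
    stop("table must be a file path or a data.frame", call. = FALSE)
  }
  required <- c("prophage_id", "genome_id", "contig_id", "contig_length",
                "start", "end", "completeness")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("prediction table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, required]
  if (nrow(df) == 0L) return(df)

  bad <- character(0)
  for (col in c("contig_length", "start", "end", "completeness")) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    nn <- which(is.na(val) & !is.na(df[[col]]))
    if (length(nn)) {
      bad <- c(bad, sprintf("line %d (%s): non-numeric %s",
                            nn + 1L, df$prophage_id[nn], col))
    }
    df[[col]] <- val
  }
  inv <- which(!is.na(df$start) & !is.na(df$end) &
                 (df$start < 1 | df$end < df$start |
                    df$end > df$contig_length))
  if (length(inv)) {
    bad <- c(bad, sprintf("line %d (%s): invalid coordinates [%s, %s] on contig of %s bp",
                          inv + 1L, df$prophage_id[inv], df$start[inv],
                          df$end[inv], df$contig_length[inv]))
  }
  cmp <- which(!is.na(df$completeness) &
                 (df$completeness < 0 | df$completeness > 100))
  if (length(cmp)) {
    bad <- c(bad, sprintf("line %d (%s): completeness outside [0, 100]",
                          cmp + 1L, df$prophage_id[cmp]))
  }
  if (length(bad)) {
    stop("malformed prediction rows:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  df
}

#' Filter prophage predictions on completeness and contig length
#'
#' Keeps a prediction iff completeness strictly exceeds `min_completeness`
#' (the survey convention ">50% completeness") and the contig holds at least
#' `min_contig` bp (non-strict, "at least 30,000 bp"). Dropped records carry
#' the rule(s) they failed.
#'
#' @param records Prediction data.frame (see [parse_predictions()]).
#' @param min_completeness Completeness threshold in percent, strict.
#' @param min_contig Contig length threshold in bp, non-strict.
#' @return A list with `kept` and `dropped` data.frames; `dropped` has an
#'   extra `reason` column.
#' @export
filter_predictions <- function(records, min_completeness = 50,
                               min_contig = 30000) {
  check_scalar_number(min_completeness, "min_completeness", 0, 100)
  check_scalar_number(min_contig, "min_contig", 0)
  ok_comp <- records$completeness > min_completeness
  ok_contig <- records$contig_length >= min_contig
  keep <- ok_comp & ok_contig
  dropped <- records[!keep, , drop = FALSE]
  if (nrow(dropped)) {
    dropped$reason <- apply(
      cbind(ifelse(!ok_comp[!keep],
                   sprintf("completeness <= %s", min_completeness), NA),
            ifelse(!ok_contig[!keep],
                   sprintf("contig < %s bp", min_contig), NA)),
      1L, function(r) paste(stats::na.omit(r), collapse = "; "))
  } else {
    dropped$reason <- character(0)
  }
  list(kept = records[keep, , drop = FALSE], dropped = dropped)
}

#' Resolve contigs carrying more than one prophage signal
#'
#' Deterministic replacement for a manual curation step: overlapping
#' prophage intervals on the same contig are merged into a single record
#' (union of coordinates, maximum completeness, member ids joined with "+");
#' non-overlapping signals on one contig stay separate. Every touched contig
#' is listed in the report.
#'
#' @param records Prediction data.frame.
#' @return A list with `records` (resolved) and `report` (data.frame of
#'   contigs whose signals were merged, with member ids). The operation is
#'   idempotent.
#' @export
resolve_multicontig <- function(records) {
  if (nrow(records) == 0L) {
    return(list(records = records,
                report = data.frame(contig_id = character(0),
                                    merged_ids = character(0))))
  }
  out <- vector("list", 0L)
  report <- list()
  for (cid in unique(records$contig_id)) {
    rows <- records[records$contig_id == cid, , drop = FALSE]
    rows <- rows[order(rows$start, rows$end), , drop = FALSE]
    if (nrow(rows) == 1L) {
      out[[length(out) + 1L]] <- rows
      next
    }
    # merge runs of overlapping intervals
    grp <- integer(nrow(rows))
    grp[1] <- 1L
    cur_end <- rows$end[1]
    for (i in seq_len(nrow(rows))[-1]) {
      if (rows$start[i] <= cur_end) {
        grp[i] <- grp[i - 1L]
        cur_end <- max(cur_end, rows$end[i])
      } else {
        grp[i] <- grp[i - 1L] + 1L
        cur_end <- rows$end[i]
      }
    }
    for (g in unique(grp)) {
      sub <- rows[grp == g, , drop = FALSE]
      if (nrow(sub) == 1L) {
        out[[length(out) + 1L]] <- sub
      } else {
        merged <- sub[1L, , drop = FALSE]
        merged$prophage_id <- paste(sub$prophage_id, collapse = "+")
        merged$start <- min(sub$start)
        merged$end <- max(sub$end)
        merged$completeness <- max(sub$completeness)
        out[[length(out) + 1L]] <- merged
        report[[length(report) + 1L]] <- data.frame(
          contig_id = cid,
          merged_ids = paste(sub$prophage_id, collapse = "+"),
          stringsAsFactors = FALSE)
      }
    }
  }
  resolved <- do.call(rbind, out)
  rownames(resolved) <- NULL
  report_df <- if (length(report)) do.call(rbind, report) else {
    data.frame(contig_id = character(0), merged_ids = character(0))
  }
  list(records = resolved, report = report_df)
}

#' Extract prophage sequences from contig sequences
#'
#' Slices `[start, end]` (1-based inclusive) out of each record's contig.
#'
#' @param records Prediction data.frame.
#' @param contigs Named character vector or `DNAStringSet` of contig
#'   sequences, names matching `contig_id`.
#' @return Named character vector of prophage sequences.
#' @export
extract_prophages <- function(records, contigs) {
  contigs <- as_seq_vector(contigs)
  missing <- setdiff(unique(records$contig_id), names(contigs))
  if (length(missing)) {
    stop("contig sequence(s) not provided: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- vapply(seq_len(nrow(records)), function(i) {
    substr(contigs[[records$contig_id[i]]], records$start[i], records$end[i])
  }, character(1))
  names(out) <- records$prophage_id
  out
}
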