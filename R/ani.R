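#' Parameters for fragment-based ANI
#'
#' The conventions follow the classic fragment-based (ANIb) procedure: the
#' query is cut into consecutive non-overlapping fragments (default 1,020
#' bp; a shorter final fragment is retained if at least `min_tail` bp), each
#' fragment is locally aligned to the whole subject, and a fragment
#' contributes iff its best alignment covers at least `min_fragment_coverage`
#' of the fragment with at least `min_fragment_identity` identity. Pair
#' identity is the alignment-length-weighted mean identity over retained
#' fragments; pair coverage is the retained aligned query bases over the
#' query length. Pairs with no retained fragment score identity 0 and
#' coverage 0 (not missing).
#'
#' Two aligner backends satisfy the same contract (best-score affine-gap
#' local alignment; a gap of length L costs `gap_open + L * gap_ext`):
#' `"seeded"` (default) restricts the exact DP to a diagonal band located by
#' shared 21-mers and skips pairs that share no 21-mer, while `"exact"` runs
#' the full dynamic program over every diagonal and is the reference
#' implementation used for oracle testing.
#'
#' @param fragment_size Query fragment length in bp.
#' @param min_tail Minimum length of the final, shorter fragment.
#' @param min_fragment_coverage Fragment retention: minimum aligned fraction
#'   of the fragment (default 0.7).
#' @param min_fragment_identity Fragment retention: minimum alignment
#'   identity as a fraction (default 0.3).
#' @param match,mismatch,gap_open,gap_ext Alignment scoring (defaults +1,
#'   -1, 5, 1; gap penalties are costs).
#' @param method `"seeded"` or `"exact"`.
#' @param seed_k k-mer size used for seeding and pair prescreening.
#' @param band_pad Extra diagonals added on each side of the seeded band.
#' @return An object of class `ani_params`.
#' @export
ani_params <- function(fragment_size = 1020L, min_tail = 100L,
                       min_fragment_coverage = 0.7,
                       min_fragment_identity = 0.3,
                       match = 1L, mismatch = -1L,
                       gap_open = 5L, gap_ext = 1L,
                       method = c("seeded", "exact"),
                       seed_k = 21L, band_pad = 50L) {
  method <- match.arg(method)
  check_scalar_number(fragment_size, "fragment_size", min = 1)
  check_scalar_number(min_tail, "min_tail", min = 1)
  check_scalar_number(min_fragment_coverage, "min_fragment_coverage", 0, 1)
  check_scalar_number(min_fragment_identity, "min_fragment_identity", 0, 1)
  check_scalar_number(seed_k, "seed_k", min = 4, max = 31)
  structure(list(fragment_size = as.integer(fragment_size),
                 min_tail = as.integer(min_tail),
                 min_fragment_coverage = min_fragment_coverage,
                 min_fragment_identity = min_fragment_identity,
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_ext = as.integer(gap_ext),
                 method = method, seed_k = as.integer(seed_k),
                 band_pad = as.integer(band_pad)),
            class = "ani_params")
}

#' Cut a sequence into ANI fragments
#'
#' Consecutive non-overlapping windows of `fragment_size` bp; the final
#' shorter window is kept only if at least `min_tail` bp.
#'
#' @param seq A single nucleotide string.
#' @inheritParams ani_params
#' @return A data.frame with columns `start`, `end`, `length` (1-based
#'   inclusive coordinates on the input); zero rows if the sequence is
#'   shorter than `min_tail`.
#' @export
fragment_sequence <- function(seq, fragment_size = 1020L, min_tail = 100L) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("seq must be a single non-empty nucleotide string", call. = FALSE)
  }
  len <- nchar(seq)
  starts <- seq.int(1L, by = fragment_size,
                    length.out = len %/% fragment_size)
  ends <- starts + fragment_size - 1L
  tail_start <- length(starts) * fragment_size + 1L
  if (len - tail_start + 1L >= min_tail) {
    starts <- c(starts, tail_start)
    ends <- c(ends, len)
  }
  data.frame(start = as.integer(starts), end = as.integer(ends),
             length = as.integer(ends - starts + 1L))
}

#' Exhaustive affine-gap local alignment (reference dynamic program)
#'
#' Best-score Smith-Waterman with affine gaps over the full dynamic-
#' programming matrix. This is the reference implementation of the aligner
#' contract behind [compute_pairwise_ani()]; use it on modest sequence
#' lengths (the full traceback matrix is kept in memory).
#'
#' @param query,subject Nucleotide strings.
#' @param match,mismatch,gap_open,gap_ext Scoring; a gap of length L costs
#'   `gap_open + L * gap_ext`.
#' @return A list: `score`, `matches`, `aln_cols` (alignment columns
#'   including gaps), `identity` (percent), 1-based `q_start`, `q_end`,
#'   `s_start`, `s_end`, and `q_aligned`.
#' @export
sw_align <- function(query, subject, match = 1L, mismatch = -1L,
                     gap_open = 5L, gap_ext = 1L) {
  if (nchar(query) == 0L || nchar(subject) == 0L) {
    stop("query and subject must be non-empty", call. = FALSE)
  }
  cpp_sw_align(query, subject, match, mismatch, gap_open, gap_ext)
}

#' Fragment-based ANI between two sequences
#'
#' @param query,subject Nucleotide strings (the comparison is asymmetric:
#'   fragments are taken from the query).
#' @param params An [ani_params()] object.
#' @return An object of class `ani_result`: `identity` and `coverage` in
#'   percent, `n_fragments`, `n_fragments_retained`, and a per-fragment
#'   data.frame `fragments`.
#' @export
compute_pairwise_ani <- function(query, subject, params = ani_params()) {
  if (!is.character(query) || length(query) != 1L || nchar(query) == 0L ||
      !is.character(subject) || length(subject) != 1L || nchar(subject) == 0L) {
    stop("query and subject must be single non-empty nucleotide strings",
         call. = FALSE)
  }
  res <- cpp_ani_pair(query, subject,
                      params$fragment_size, params$min_tail,
                      params$min_fragment_coverage,
                      params$min_fragment_identity,
                      params$match, params$mismatch,
                      params$gap_open, params$gap_ext,
                      if (params$method == "seeded") 0L else 1L,
                      params$seed_k, params$band_pad)
  structure(res, class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI: identity %.3f%%, coverage %.3f%% (%d/%d fragments retained)\n",
              x$identity, x$coverage, x$n_fragments_retained, x$n_fragments))
  invisible(x)
}

#' All-versus-all fragment-based ANI
#'
#' Computes the asymmetric identity and coverage matrices over all ordered
#' pairs (row = query, column = subject), the input of species-level
#' clustering.
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet`
#'   with unique ids.
#' @param params An [ani_params()] object.
#' @return An object of class `ani_matrix`: list with `ids`, `identity` and
#'   `coverage` (id x id percent matrices), `n_fragments_retained`, and the
#'   `params` used.
#' @export
compute_ani_matrix <- function(sequences, params = ani_params()) {
  seqs <- as_seq_vector(sequences)
  if (length(seqs) < 1L) stop("need at least one sequence", call. = FALSE)
  res <- cpp_ani_matrix(unname(seqs),
                        params$fragment_size, params$min_tail,
                        params$min_fragment_coverage,
                        params$min_fragment_identity,
                        params$match, params$mismatch,
                        params$gap_open, params$gap_ext,
                        if (params$method == "seeded") 0L else 1L,
                        params$seed_k, params$band_pad)
  ids <- names(seqs)
  dimnames(res$identity) <- list(ids, ids)
  dimnames(res$coverage) <- list(ids, ids)
  dimnames(res$n_fragments_retained) <- list(ids, ids)
  structure(list(ids = ids, identity = res$identity,
                 coverage = res$coverage,
                 n_fragments_retained = res$n_fragments_retained,
                 params = params),
            class = "ani_matrix")
}

#' Construct an ani_matrix from existing matrices
#'
#' @param identity,coverage Square percent matrices with identical id
#'   dimnames (row = query).
#' @return An `ani_matrix`.
#' @export
ani_matrix <- function(identity, coverage) {
  if (!is.matrix(identity) || !is.matrix(coverage) ||
      !identical(dim(identity), dim(coverage)) ||
      nrow(identity) != ncol(identity)) {
    stop("identity and coverage must be square matrices of equal dimension",
         call. = FALSE)
  }
  ids <- rownames(identity)
  if (is.null(ids) || !identical(ids, colnames(identity)) ||
      !identical(ids, rownames(coverage)) ||
      !identical(ids, colnames(coverage))) {
    stop("matrices must share identical id dimnames", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate ids", call. = FALSE)
  rng <- range(identity, coverage)
  if (rng[1] < 0 || rng[2] > 100) {
    stop("values must lie in [0, 100]", call. = FALSE)
  }
  structure(list(ids = ids, identity = identity, coverage = coverage,
                 n_fragments_retained = NULL, params = NULL),
            class = "ani_matrix")
}

#' @export
print.ani_matrix <- function(x, ...) {
  n <- length(x$ids)
  off <- x$identity[row(x$identity) != col(x$identity)]
  cat(sprintf("ANI matrix over %d sequences\n", n))
  if (length(off)) {
    cat(sprintf("  off-diagonal identity: median %.2f%%, max %.2f%%; %0.1f%% of pairs at 0\n",
                stats::median(off), max(off), 100 * mean(off == 0)))
  }
  invisible(x)
}

#' Write / read an ANI matrix pair as tab-delimited files
#'
#' `write_ani_matrix()` writes `<prefix>_identity.tsv` and
#' `<prefix>_coverage.tsv` with an id header row and id first column.
#' `read_ani_matrix()` reads them back; matrices whose values are fractions
#' in `[0, 1]` (the output dialect of the classic ANI tools) are rescaled to
#' percent on import.
#'
#' @param mat An `ani_matrix`.
#' @param prefix Path prefix for the two files.
#' @return `write_ani_matrix()`: invisibly, the two paths;
#'   `read_ani_matrix()`: an `ani_matrix`.
#' @export
write_ani_matrix <- function(mat, prefix) {
  stopifnot(inherits(mat, "ani_matrix"))
  paths <- paste0(prefix, c("_identity.tsv", "_coverage.tsv"))
  for (i in 1:2) {
    m <- if (i == 1) mat$identity else mat$coverage
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_ani_matrix
#' @param identity_file,coverage_file Paths to the two tab-delimited
#'   matrices (used instead of `prefix` if given).
#' @export
read_ani_matrix <- function(prefix = NULL, identity_file = NULL,
                            coverage_file = NULL) {
  if (is.null(identity_file)) identity_file <- paste0(prefix, "_identity.tsv")
  if (is.null(coverage_file)) coverage_file <- paste0(prefix, "_coverage.tsv")
  read_one <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    if (max(m) <= 1 + 1e-12) m <- m * 100   # fraction dialect
    m
  }
  idm <- read_one(identity_file)
  cvm <- read_one(coverage_file)
  cvm <- cvm[rownames(idm), colnames(idm), drop = FALSE]
  ani_matrix(idm, cvm)
}
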