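#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so seeded operations do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a reproducible sub-seed from a master seed; stays below 2^31 - 1
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) + 104729 * as.double(k)) %% 2147483646L + 1)
}

# locale-independent sort, used for every deterministic tie-break
sort_ids <- function(x) sort(x, method = "radix")

check_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}

# coerce a DNAStringSet or character vector to a named character vector
as_seq_vector <- function(sequences) {
  if (methods::is(sequences, "DNAStringSet")) {
    out <- as.character(sequences)
  } else if (is.character(sequences)) {
    out <- sequences
  } else {
    stop("sequences must be a character vector or a Biostrings::DNAStringSet",
         call. = FALSE)
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop("all sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(out))) {
    stop("duplicate sequence ids: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "),
         call. = FALSE)
  }
  out
}
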