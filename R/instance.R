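#' Create an SCSP instance
#'
#' An instance of the shortest common supersequence problem is a finite
#' alphabet together with a set of strings over it. Empty strings are
#' dropped with a warning (they are embedded by anything and carry no
#' information); duplicate strings are kept, since they affect front counts
#' in Majority Merge and the probability product of the beam-search
#' heuristic. Symbols are case-sensitive.
#'
#' @param strings character vector of input sequences (each a plain string).
#' @param alphabet optional character vector of distinct single characters.
#'   Defaults to the characters observed in `strings`, in order of first
#'   appearance. Iteration order of the alphabet is fixed and meaningful:
#'   deterministic tie-breaks use it.
#' @param id optional instance label.
#' @return An object of class `scs_instance`: a list with elements
#'   `strings`, `alphabet`, `id`, plus precomputed per-string character
#'   vectors (`chars`), integer encodings (`enc`, 1-based alphabet indices)
#'   and `lengths`.
#' @examples
#' inst <- scs_instance(c("ab", "ba"))
#' inst$alphabet
#' @export
scs_instance <- function(strings, alphabet = NULL, id = NULL) {
  stopifnot(is.character(strings), length(strings) >= 1)
  empty <- !nzchar(strings)
  if (any(empty)) {
    warning(sum(empty), " empty string(s) dropped from instance")
    strings <- strings[!empty]
  }
  if (length(strings) == 0) stop("instance has no nonempty strings")
  chars <- strsplit(strings, "", fixed = TRUE)
  if (is.null(alphabet)) {
    alphabet <- unique(unlist(chars, use.names = FALSE))
  } else {
    alphabet <- as.character(alphabet)
    if (anyDuplicated(alphabet)) stop("alphabet symbols must be distinct")
    if (any(nchar(alphabet) != 1)) stop("alphabet symbols must be single characters")
  }
  if (length(alphabet) < 1) stop("alphabet must have at least one symbol")
  enc <- lapply(chars, function(v) {
    e <- match(v, alphabet)
    if (anyNA(e)) stop("string contains character(s) outside the alphabet: ",
                       paste(unique(v[is.na(e)]), collapse = ", "))
    e
  })
  structure(
    list(strings = strings, alphabet = alphabet, id = id, chars = chars,
         enc = enc, lengths = nchar(strings)),
    class = "scs_instance"
  )
}

#' @export
print.scs_instance <- function(x, ...) {
  cat("SCSP instance", if (!is.null(x$id)) paste0("'", x$id, "'"), "\n")
  cat("  alphabet (q=", length(x$alphabet), "): ",
      paste(x$alphabet, collapse = ""), "\n", sep = "")
  cat("  strings (m=", length(x$strings), "): lengths ",
      paste(x$lengths, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# 0-based integer encoding handed to the C++ routines
.enc0 <- function(inst) lapply(inst$enc, function(v) v - 1L)

# decode a 0-based integer sequence back to a string
.dec <- function(seq0, alphabet) paste(alphabet[seq0 + 1L], collapse = "")

#' Generate a seeded uniform-random instance
#'
#' Builds a benchmark instance in which every string is drawn i.i.d.
#' uniformly over the alphabet. The defaults reproduce the classical
#' random benchmark layout for this problem: eight strings, four of
#' length 40 and four of length 80, with the alphabet size varied across
#' subsets (2--24).
#'
#' @param q alphabet size (>= 1).
#' @param lengths integer vector of string lengths.
#' @param seed integer seed; identical `(q, lengths, seed)` yields a
#'   byte-identical instance.
#' @param alphabet optional alphabet; defaults to the first `q` lowercase
#'   letters.
#' @param id optional label; defaults to `"rand-q<q>-s<seed>"`.
#' @return An [scs_instance()].
#' @examples
#' inst <- generate_random_instance(4, seed = 1)
#' inst$lengths
#' @export
generate_random_instance <- function(q, lengths = c(40, 40, 40, 40, 80, 80, 80, 80),
                                     seed = 1L, alphabet = NULL, id = NULL) {
  stopifnot(q >= 1, all(lengths >= 1))
  if (is.null(alphabet)) {
    if (q > 26) stop("default alphabet supports q <= 26; supply `alphabet`")
    alphabet <- letters[seq_len(q)]
  }
  stopifnot(length(alphabet) == q)
  set.seed(as.integer(seed))
  strings <- vapply(lengths, function(n) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
  }, character(1))
  if (is.null(id)) id <- sprintf("rand-q%d-s%d", q, as.integer(seed))
  scs_instance(strings, alphabet = alphabet, id = id)
}

#' Read / write an instance in plain-text format
#'
#' The plain-text format holds one sequence per line. Blank lines and lines
#' starting with `#` are ignored, except for an optional header of the form
#' `#alphabet: abc` which fixes the alphabet and its symbol order (symbols
#' are given as one concatenated run of characters). Without the header the
#' alphabet is the set of observed characters in first-appearance order.
#'
#' @param path file path.
#' @param id optional instance label; defaults to the file name.
#' @return [read_instance_text()] returns an [scs_instance()];
#'   [write_instance_text()] invisibly returns `path`.
#' @examples
#' f <- tempfile()
#' write_instance_text(scs_instance(c("ab", "ba")), f)
#' read_instance_text(f)
#' @export
read_instance_text <- function(path, id = NULL) {
  lines <- readLines(path)
  alpha <- NULL
  hdr <- grepl("^#alphabet:", lines)
  if (any(hdr)) {
    spec <- sub("^#alphabet:\\s*", "", lines[which(hdr)[1]])
    alpha <- strsplit(spec, "", fixed = TRUE)[[1]]
  }
  seqs <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(seqs) == 0) stop("no sequences found in ", path)
  if (is.null(id)) id <- basename(path)
  scs_instance(trimws(seqs), alphabet = alpha, id = id)
}

#' @rdname read_instance_text
#' @param inst an [scs_instance()].
#' @export
write_instance_text <- function(inst, path) {
  stopifnot(inherits(inst, "scs_instance"))
  writeLines(c(paste0("#alphabet: ", paste(inst$alphabet, collapse = "")),
               inst$strings), path)
  invisible(path)
}

#' Read an instance from a FASTA file
#'
#' One instance string per FASTA record, record order preserved; sequences
#' are upper-cased. Empty records are dropped with a warning. The alphabet
#' is inferred from the observed characters; with `type = "dna"` a warning
#' is raised if characters outside `ACGT` occur.
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @param type `"auto"` (no alphabet check), `"dna"` or `"protein"`.
#' @param id optional label; defaults to the file name.
#' @return An [scs_instance()].
#' @export
read_fasta <- function(path, type = c("auto", "dna", "protein"), id = NULL) {
  type <- match.arg(type)
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("read_fasta() requires the Biostrings package")
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  if (is.null(id)) id <- basename(path)
  if (type == "dna") {
    obs <- unique(unlist(strsplit(seqs, "", fixed = TRUE)))
    bad <- setdiff(obs, c("A", "C", "G", "T"))
    if (length(bad) > 0)
      warning("DNA file contains non-ACGT characters: ",
              paste(bad, collapse = ", "))
  }
  scs_instance(seqs, id = id)
}
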