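## Catabolite-responsive element (cre) analysis: degenerate-consensus
## scanning on both strands, mismatch scoring, position frequency matrices
## with information content, and key-position classification.

#' Degenerate cre consensus
#'
#' The cre operator consensus bound by CcpA, `TGNNANCGNTTNCA` (14 bp, 9
#' fixed positions), expressed in IUPAC nucleotide codes. Positions are
#' 1-based in reports.
#'
#' @param pattern IUPAC string, length >= 1.
#' @return A `cre_consensus` object (list with `pattern`, `length`,
#'   `allowed`: per-position character vectors of accepted bases).
#' @export
cre_consensus <- function(pattern = "TGNNANCGNTTNCA") {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    abort("pattern must be a non-empty string")
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "")[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- setdiff(chars, names(map))
  if (length(bad))
    abort("non-IUPAC characters in consensus: %s", paste(bad, collapse = ""))
  allowed <- lapply(chars, function(ch) strsplit(map[[ch]], "")[[1]])
  structure(list(pattern = pattern, length = length(chars),
                 allowed = allowed),
            class = "cre_consensus")
}

#' @export
print.cre_consensus <- function(x, ...) {
  cat(sprintf("<cre_consensus> %s (%d bp)\n", x$pattern, x$length))
  invisible(x)
}

check_site_string <- function(site, len = NULL) {
  if (!is.character(site) || length(site) != 1L)
    abort("site must be a single string")
  site <- toupper(site)
  if (grepl("[^ACGT]", site))
    abort("site contains non-ACGT characters: '%s'", site)
  if (!is.null(len) && nchar(site) != len)
    abort("site length %d does not match consensus length %d",
          nchar(site), len)
  site
}

#' Mismatch count of a site against a degenerate consensus
#'
#' Counts positions where the site base is not in the IUPAC set of the
#' consensus character; `N` in the consensus matches everything.
#'
#' @param site Nucleotide string (A/C/G/T), same length as the consensus.
#' @param consensus A [cre_consensus()] (default: the cre consensus).
#' @return Integer mismatch count.
#' @examples
#' match_consensus("TGAAAACGATTACA") # 0
#' @export
match_consensus <- function(site, consensus = cre_consensus()) {
  stopifnot(inherits(consensus, "cre_consensus"))
  site <- check_site_string(site, consensus$length)
  b <- strsplit(site, "")[[1]]
  sum(vapply(seq_along(b),
             function(i) !(b[i] %in% consensus$allowed[[i]]), TRUE))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(s) {
  vapply(s, function(one)
    paste(rev(COMPLEMENT[strsplit(toupper(one), "")[[1]]]), collapse = ""),
    "", USE.NAMES = FALSE)
}

# vectorised mismatch counts of every window of `seq_chars` vs consensus
window_mismatches <- function(seq_chars, consensus) {
  L <- consensus$length
  n <- length(seq_chars)
  if (n < L) return(integer())
  mm <- integer(n - L + 1L)
  for (k in seq_len(L))
    mm <- mm + !(seq_chars[k:(n - L + k)] %in% consensus$allowed[[k]])
  mm
}

#' Scan sequences for cre sites on both strands
#'
#' Every window (both strands) with at most `max_mismatch` mismatches to the
#' consensus is reported. Coordinates are 0-based half-open on the forward
#' strand; reverse-strand hits report the reverse complement of the forward
#' subsequence as `site_seq` (i.e. the motif-oriented bases). Overlapping
#' hits are all reported; a palindromic match counts once per strand.
#'
#' @param sequences A named character vector, or a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param consensus A [cre_consensus()].
#' @param max_mismatch Maximum mismatches, >= 0.
#' @return A data.frame (class `site_hits`) with columns `seq_id`, `start`,
#'   `end`, `strand`, `mismatches`, `site_seq`, sorted by
#'   (seq_id, start, strand). Empty input yields an empty frame.
#' @export
scan_cre_sites <- function(sequences, consensus = cre_consensus(),
                           max_mismatch = 0L) {
  stopifnot(inherits(consensus, "cre_consensus"))
  if (!is.numeric(max_mismatch) || max_mismatch < 0)
    abort("max_mismatch must be >= 0")
  seqs <- as_named_sequences(sequences)
  L <- consensus$length
  rows <- list()
  for (id in names(seqs)) {
    s <- toupper(seqs[[id]])
    if (grepl("[^ACGT]", s))
      abort("sequence '%s' contains non-ACGT characters", id)
    n <- nchar(s)
    if (n < L) next
    fwd <- strsplit(s, "")[[1]]
    mm_f <- window_mismatches(fwd, consensus)
    hit_f <- which(mm_f <= max_mismatch)
    rc_chars <- rev(unname(COMPLEMENT[fwd]))
    mm_r <- window_mismatches(rc_chars, consensus)
    hit_r <- which(mm_r <= max_mismatch)
    rc <- if (length(hit_r)) paste(rc_chars, collapse = "") else ""
    if (length(hit_f))
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, start = hit_f - 1L, end = hit_f - 1L + L, strand = "+",
        mismatches = mm_f[hit_f],
        site_seq = substring(s, hit_f, hit_f + L - 1L))
    if (length(hit_r))
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, start = n - (hit_r - 1L) - L,
        end = n - (hit_r - 1L), strand = "-",
        mismatches = mm_r[hit_r],
        site_seq = substring(rc, hit_r, hit_r + L - 1L))
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(seq_id = character(), start = integer(),
                         end = integer(), strand = character(),
                         mismatches = integer(), site_seq = character())
  out <- out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("site_hits", "data.frame")
  out
}

as_named_sequences <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    out <- as.character(sequences)
  } else if (is.character(sequences) && length(sequences) == 1L &&
             file.exists(sequences) && !grepl("^[ACGTNacgtn]+$", sequences)) {
    out <- as.character(Biostrings::readDNAStringSet(sequences))
  } else if (is.character(sequences)) {
    out <- sequences
    if (is.null(names(out)) && length(out))
      names(out) <- paste0("seq", seq_along(out))
  } else abort("sequences must be a DNAStringSet, named character, or FASTA path")
  if (anyDuplicated(names(out))) abort("duplicate sequence ids")
  out
}

#' Position frequency matrix over aligned sites
#'
#' Per-position base counts plus a pseudocount; column frequencies and the
#' information content per position under a uniform background,
#' \eqn{IC_j = 2 + \sum_b p_{bj} \log_2 p_{bj}} bits (0 for a uniform
#' column, 2 for an invariant one).
#'
#' @param sites Character vector of equal-length A/C/G/T strings, >= 1.
#' @param pseudocount Added to every cell (default 0.5).
#' @return A `pf_matrix`: list with `counts` (4xL, rows A,C,G,T), `probs`,
#'   `info_content` (per-position bits), `n_sites`, `pseudocount`.
#' @export
build_pfm <- function(sites, pseudocount = 0.5) {
  if (!length(sites)) abort("need at least one site")
  assert_scalar_num(pseudocount, "pseudocount", 0)
  sites <- vapply(sites, check_site_string, "", USE.NAMES = FALSE)
  L <- nchar(sites[1])
  if (any(nchar(sites) != L)) abort("ragged site lengths rejected")
  m <- do.call(rbind, strsplit(sites, ""))
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(L), function(j)
    vapply(bases, function(b) sum(m[, j] == b) + pseudocount, 0), numeric(4))
  rownames(counts) <- bases
  probs <- sweep(counts, 2L, colSums(counts), `/`)
  ic <- apply(probs, 2L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  structure(list(counts = counts, probs = probs, info_content = ic,
                 n_sites = length(sites), pseudocount = pseudocount),
            class = "pf_matrix")
}

#' @export
print.pf_matrix <- function(x, ...) {
  cat(sprintf("<pf_matrix> %d sites x %d positions, pseudocount %g\n",
              x$n_sites, ncol(x$counts), x$pseudocount))
  cat("  info content (bits):",
      paste(sprintf("%.2f", x$info_content), collapse = " "), "\n")
  invisible(x)
}

#' Classify a 14-mer cre site by its key positions
#'
#' Down-regulated-gene cre sites carry C7, G8 and C13 (1-based positions);
#' sites upstream of up-regulated genes tend to deviate at those positions
#' while retaining T10. A site is `"consensus-like"` when C7, G8 and C13 are
#' all present, `"deviant"` otherwise; a missing T10 is flagged atypical.
#'
#' @param site A 14-character A/C/G/T string.
#' @return List with `label`, booleans `has_C7`, `has_G8`, `has_C13`,
#'   `has_T10`, and `atypical` (T10 absent).
#' @export
classify_site <- function(site) {
  site <- check_site_string(site, 14L)
  b <- strsplit(site, "")[[1]]
  has <- list(has_C7 = b[7] == "C", has_G8 = b[8] == "G",
              has_C13 = b[13] == "C", has_T10 = b[10] == "T")
  c(list(label = if (has$has_C7 && has$has_G8 && has$has_C13)
           "consensus-like" else "deviant",
         atypical = !has$has_T10), has)
}
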