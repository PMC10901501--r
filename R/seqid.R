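# Pairwise protein sequence identity for train/test stratification:
# Smith-Waterman local alignment under BLOSUM62 with affine gaps (first
# gapped position -11, each extension -1), identity = exact matches over
# query length, binned low/medium/high.

#' Alignment parameters
#'
#' @param gap_open Score of the first gapped position (default -11).
#' @param gap_extend Score of each further gapped position (default -1).
#' @param matrix_name Substitution matrix (only `"BLOSUM62"` shipped).
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(gap_open = -11L, gap_extend = -1L,
                             matrix_name = "BLOSUM62") {
  stopifnot(gap_open <= gap_extend, gap_extend <= 0)
  structure(list(gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 matrix_name = matrix_name, mode = "local"),
            class = "alignment_params")
}

clean_seq <- function(s) {
  s <- toupper(gsub("[^A-Za-z*]", "", s))
  if (!nzchar(s)) stop("empty sequence")
  # residues outside the substitution alphabet count as unknown
  known <- strsplit("ARNDCQEGHILKMFPSTWYVBZX*", "")[[1]]
  ch <- strsplit(s, "")[[1]]
  ch[!(ch %in% known)] <- "X"
  paste(ch, collapse = "")
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under BLOSUM62 with affine gap scoring in the
#' stated convention: opening a gap costs `gap_open` for its first
#' position and `gap_extend` for each extension. Unknown residues are
#' mapped to X, which scores as a mismatch.
#'
#' @param query,target Amino-acid sequences (one-letter codes).
#' @param params An [alignment_params()].
#' @return A list with `score`, `pairs` (two-column matrix of aligned
#'    1-based positions, gaps excluded), `matches` (exact residue matches,
#'   X never matching), and the aligned strings.
#' @export
smith_waterman <- function(query, target, params = alignment_params()) {
  q <- clean_seq(query); t <- clean_seq(target)
  mat <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(t),
    type = "local", substitutionMatrix = mat,
    gapOpening = -(params$gap_open - params$gap_extend),
    gapExtension = -params$gap_extend)
  ap <- as.character(Biostrings::pattern(pa))
  as_ <- as.character(Biostrings::subject(pa))
  qs <- Biostrings::start(Biostrings::pattern(pa))
  ts <- Biostrings::start(Biostrings::subject(pa))
  ac <- strsplit(ap, "")[[1]]; bc <- strsplit(as_, "")[[1]]
  qi <- cumsum(ac != "-") + qs - 1L
  ti <- cumsum(bc != "-") + ts - 1L
  keep <- ac != "-" & bc != "-"
  pairs <- cbind(query = qi[keep], target = ti[keep])
  matches <- sum(ac[keep] == bc[keep] & ac[keep] != "X")
  list(score = Biostrings::score(pa), pairs = pairs, matches = matches,
       aligned_query = ap, aligned_target = as_)
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Maximum pairwise sequence identity between chain sets
#'
#' Identity of one chain pair is 100 * matches / query length; the result
#' is the maximum over all query x reference chain pairs. Bins follow the
#' printed intervals low [0, 30), medium [30, 90], high (90, 100] (the
#' boundaries 30 and 90 both fall in medium).
#'
#' @param query_chains,reference_chains Character vectors of sequences.
#' @param params An [alignment_params()].
#' @return A list of class `identity_result`: `identity` (percent),
#'   `matches`, `query_length`, `bin`, and the attaining pair indices.
#' @export
max_identity <- function(query_chains, reference_chains,
                         params = alignment_params()) {
  stopifnot(length(query_chains) > 0, length(reference_chains) > 0)
  best <- list(identity = -1)
  for (qi in seq_along(query_chains)) {
    qlen <- nchar(clean_seq(query_chains[qi]))
    for (ri in seq_along(reference_chains)) {
      sw <- smith_waterman(query_chains[qi], reference_chains[ri], params)
      ident <- 100 * sw$matches / qlen
      if (ident > best$identity) {
        best <- list(identity = ident, matches = sw$matches,
                     query_length = qlen, query_chain = qi,
                     reference_chain = ri)
      }
    }
  }
  best$bin <- identity_bin(best$identity)
  class(best) <- "identity_result"
  best
}

identity_bin <- function(identity) {
  if (identity < 30) "low" else if (identity <= 90) "medium" else "high"
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
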