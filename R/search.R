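## Self-contained tBLASTx-style engine: both nucleotide sequences are
## translated in all six reading frames, stop-delimited protein segments are
## aligned locally (affine Smith-Waterman, BLOSUM62), and raw scores are
## converted to Karlin-Altschul E-values E = K * m * n * exp(-lambda * S).
## Alignments never cross a stop codon; the ungapped (lambda, K) pair is
## applied to gapped scores as a documented approximation — the loss caller
## is calibrated against this engine, not against any external BLAST.

.search_cache <- new.env(parent = emptyenv())

## BLOSUM62 from Biostrings' data, loaded once per session.
blosum62_matrix <- function() {
  if (is.null(.search_cache$BLOSUM62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    .search_cache$BLOSUM62 <- env$BLOSUM62
  }
  .search_cache$BLOSUM62
}

#' Scoring scheme for the translated search
#'
#' @param matrix_name Substitution matrix name; only `"BLOSUM62"` ships
#'   (taken from \pkg{Biostrings}' data).
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters (nats).
#' @return List of class `scoring_scheme` including the substitution
#'   matrix itself (`$matrix`).
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L, lambda = 0.3176, K = 0.134) {
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be > 0")
  if (matrix_name != "BLOSUM62") stop("only BLOSUM62 is available")
  structure(list(matrix_name = matrix_name, matrix = blosum62_matrix(),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Six-frame translation
#'
#' Translates frames +1, +2, +3 of the forward strand and -1, -2, -3 of the
#' reverse complement under the standard genetic code. Stop codons are
#' rendered `*`, codons containing `N` become `X`, trailing partial codons
#' are dropped.
#'
#' @param dna A [Biostrings::DNAString], or a character string over
#'   `A`, `C`, `G`, `T`, `N` of length >= 3.
#' @return Named character vector of the six translations, names
#'   `"+1" ... "-3"`.
#' @examples
#' six_frame_translate("ATGGCC")
#' @export
six_frame_translate <- function(dna) {
  dna <- toupper(as.character(dna))
  if (nchar(dna) < 3) stop("sequence must be at least 3 nt")
  if (grepl("[^ACGTN]", dna)) stop("sequence must be over A, C, G, T, N")
  code <- genetic_code_table()
  rc <- revcomp_string(dna)
  one <- function(s, off) {
    len <- nchar(s) - off
    len <- len - (len %% 3)
    if (len < 3) return("")
    starts <- seq.int(off + 1L, off + len - 2L, by = 3L)
    aa <- unname(code[substring(s, starts, starts + 2L)])
    aa[is.na(aa)] <- "X"                   # codons containing N
    paste(aa, collapse = "")
  }
  c("+1" = one(dna, 0L), "+2" = one(dna, 1L), "+3" = one(dna, 2L),
    "-1" = one(rc, 0L), "-2" = one(rc, 1L), "-3" = one(rc, 2L))
}

## standard genetic code (from Biostrings), cached; stops are "*"
genetic_code_table <- function() {
  if (is.null(.search_cache$code)) {
    .search_cache$code <- Biostrings::GENETIC_CODE
  }
  .search_cache$code
}

revcomp_string <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

## Map protein characters to row indices of the substitution matrix.
aa_indices <- function(aa, sub) {
  i <- match(strsplit(aa, "", fixed = TRUE)[[1]], rownames(sub))
  i[is.na(i)] <- match("X", rownames(sub))
  i - 1L  # 0-based for C++
}

#' Local protein alignment (affine Smith-Waterman)
#'
#' Returns the single best-scoring local alignment of two protein
#' sequences under the scheme's substitution matrix and affine gap costs,
#' with score 0 (and NA spans) when no positive-scoring pair exists.
#'
#' @param query_aa,subject_aa Non-empty protein strings.
#' @param scoring A [scoring_scheme()].
#' @return List with `raw_score`, `qstart`, `qend`, `sstart`, `send`
#'   (1-based amino-acid coordinates).
#' @examples
#' local_align("MKV", "MKV")$raw_score  # 5 + 5 + 4 = 14
#' @export
local_align <- function(query_aa, subject_aa, scoring = scoring_scheme()) {
  if (!nzchar(query_aa) || !nzchar(subject_aa)) {
    stop("sequences must be non-empty")
  }
  sub <- scoring$matrix
  res <- .cpp_sw_affine(aa_indices(query_aa, sub),
                        aa_indices(subject_aa, sub),
                        sub, scoring$gap_open, scoring$gap_extend)
  list(raw_score = res$score, qstart = res$qstart, qend = res$qend,
       sstart = res$sstart, send = res$send)
}

#' Karlin-Altschul E-value and bit score
#'
#' `E = K * m * n * exp(-lambda * S)`; the bit score is
#' `(lambda * S - log(K)) / log(2)`. Raw lengths are used (no edge-effect
#' correction).
#'
#' @param raw_score Raw alignment score S.
#' @param m,n Query and subject lengths in amino acids (>= 1).
#' @param scoring A [scoring_scheme()].
#' @return E-value (numeric scalar).
#' @examples
#' karlin_evalue(50, 100, 1000)
#' @export
karlin_evalue <- function(raw_score, m, n, scoring = scoring_scheme()) {
  if (m < 1 || n < 1) stop("m and n must be >= 1")
  scoring$K * m * n * exp(-scoring$lambda * raw_score)
}

#' @rdname karlin_evalue
#' @export
bit_score <- function(raw_score, scoring = scoring_scheme()) {
  (scoring$lambda * raw_score - log(scoring$K)) / log(2)
}

## Split a frame translation into stop-free segments, keeping each
## segment's 1-based amino-acid offset within the frame.
stop_segments <- function(aa) {
  if (!nzchar(aa)) return(data.frame(start = integer(), seq = character()))
  parts <- strsplit(aa, "", fixed = TRUE)[[1]]
  stops <- which(parts == "*")
  bounds <- c(0L, stops, length(parts) + 1L)
  segs <- lapply(seq_len(length(bounds) - 1L), function(i) {
    from <- bounds[i] + 1L; to <- bounds[i + 1L] - 1L
    if (to < from) return(NULL)
    data.frame(start = from,
               seq = paste(parts[from:to], collapse = ""))
  })
  do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
}

## Convert a 1-based aa span within frame f (1,2,3 on the given strand) to
## nucleotide coordinates on that strand's sequence, then (for negative
## frames) back to the forward coordinate system of length L.
aa_span_to_nt <- function(frame, aa_start, aa_end, L) {
  f <- abs(frame)
  nt <- c(f + 3L * (aa_start - 1L), f + 3L * aa_end - 1L)
  if (frame < 0) nt <- c(L - nt[2] + 1L, L - nt[1] + 1L)
  nt
}

#' Six-frame translated search
#'
#' Aligns every stop-delimited protein segment of each query frame against
#' every segment of each subject frame (36 frame pairs) and reports hits
#' with E-value below `threshold`, mapped back to 1-based closed nucleotide
#' coordinates on the forward strands of the original sequences (the frame
#' signs carry the strands). Segment pairs whose maximum attainable score
#' cannot reach the threshold are skipped (a sound bound: E is monotone
#' decreasing in the score).
#'
#' @param query_dna,subject_dna DNA sequences (character or
#'   [Biostrings::DNAString]), each >= 3 nt.
#' @param scoring A [scoring_scheme()].
#' @param threshold Report hits with `evalue < threshold` (default `1e-5`;
#'   use `Inf` to keep every positive-scoring alignment).
#' @return Data frame of class `search_hits`, sorted by E-value:
#'   `query_frame`, `subject_frame`, `raw_score`, `bit_score`, `evalue`,
#'   `qstart`, `qend`, `sstart`, `send`.
#' @examples
#' q <- "ATGGCTGCTAAGGTTCCTGGTATGGCTGCTAAGGTT"
#' translated_search(q, paste0("AAACCC", q, "GGGTTT"), threshold = 1)
#' @export
translated_search <- function(query_dna, subject_dna,
                              scoring = scoring_scheme(),
                              threshold = 1e-5) {
  if (threshold <= 0) stop("threshold must be > 0")
  qtr <- six_frame_translate(query_dna)
  str_ <- six_frame_translate(subject_dna)
  Lq <- length(Biostrings::DNAString(query_dna))
  Ls <- length(Biostrings::DNAString(subject_dna))
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  max_diag <- max(diag(scoring$matrix))
  hits <- list()
  for (qi in seq_along(frames)) {
    qsegs <- stop_segments(qtr[qi])
    m_frame <- nchar(qtr[qi])
    if (m_frame == 0) next
    for (si in seq_along(frames)) {
      ssegs <- stop_segments(str_[si])
      n_frame <- nchar(str_[si])
      if (n_frame == 0) next
      for (a in seq_len(nrow(qsegs))) {
        qa <- qsegs$seq[a]
        if (!nzchar(qa)) next
        for (b in seq_len(nrow(ssegs))) {
          sb <- ssegs$seq[b]
          if (!nzchar(sb)) next
          cap <- max_diag * min(nchar(qa), nchar(sb))
          if (is.finite(threshold) &&
              karlin_evalue(cap, m_frame, n_frame, scoring) >= threshold) {
            next
          }
          al <- local_align(qa, sb, scoring)
          if (al$raw_score <= 0) next
          ev <- karlin_evalue(al$raw_score, m_frame, n_frame, scoring)
          if (ev >= threshold) next
          qspan <- aa_span_to_nt(frames[qi],
                                 qsegs$start[a] + al$qstart - 1L,
                                 qsegs$start[a] + al$qend - 1L, Lq)
          sspan <- aa_span_to_nt(frames[si],
                                 ssegs$start[b] + al$sstart - 1L,
                                 ssegs$start[b] + al$send - 1L, Ls)
          hits[[length(hits) + 1L]] <- data.frame(
            query_frame = frames[qi], subject_frame = frames[si],
            raw_score = al$raw_score,
            bit_score = bit_score(al$raw_score, scoring),
            evalue = ev,
            qstart = qspan[1], qend = qspan[2],
            sstart = sspan[1], send = sspan[2])
        }
      }
    }
  }
  out <- if (length(hits) == 0) {
    data.frame(query_frame = integer(), subject_frame = integer(),
               raw_score = integer(), bit_score = numeric(),
               evalue = numeric(), qstart = integer(), qend = integer(),
               sstart = integer(), send = integer())
  } else {
    do.call(rbind, hits)
  }
  out <- out[order(out$evalue), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("search_hits", "data.frame")
  out
}
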