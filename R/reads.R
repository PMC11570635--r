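# Amplicon read handling: a synthetic vgsc target-site reference, a
# deterministic L/F/NHEJ read classifier (anchored target-window extraction,
# a narrow-scope stand-in for an amplicon genotyping pipeline), and a
# mixture read generator for round-trip testing.

#' Amplicon reference for target-site classification
#'
#' Describes the PCR amplicon spanning the gRNA-F cleavage site: the amplicon
#' sequence, the protospacer (target-site) window, and the position and
#' identities of the codon-1014 variants to call.
#'
#' @param sequence Amplicon nucleotide sequence (A/C/G/T string).
#' @param target_start,target_end 1-based inclusive bounds of the target-site
#'   window within `sequence`.
#' @param codon_start 1-based position of the first base of codon 1014
#'   (must lie inside the target window).
#' @param codon_L,codon_F The 3-nt codon spelling of the wild-type 1014L and
#'   resistant 1014F alleles (must differ).
#' @return An object of class `amplicon_reference`.
#' @export
amplicon_reference <- function(sequence, target_start, target_end,
                               codon_start, codon_L = "CTT",
                               codon_F = "TTT") {
  sequence <- toupper(sequence)
  stopifnot(
    is.character(sequence), length(sequence) == 1L,
    grepl("^[ACGT]+$", sequence),
    target_start >= 1, target_end <= nchar(sequence),
    target_start < target_end,
    codon_start >= target_start, codon_start + 2L <= target_end,
    nchar(codon_L) == 3L, nchar(codon_F) == 3L, codon_L != codon_F
  )
  structure(
    list(sequence = sequence, target_start = as.integer(target_start),
         target_end = as.integer(target_end),
         codon_start = as.integer(codon_start),
         codon_L = toupper(codon_L), codon_F = toupper(codon_F)),
    class = "amplicon_reference"
  )
}

#' Synthetic vgsc amplicon reference
#'
#' A fully synthetic stand-in for the vgsc amplicon (the real amplicon
#' sequence and protospacer are not published with the assay): 150 nt with a
#' 20-nt target window at positions 61-80 and codon 1014 at 73-75, using the
#' canonical kdr codon change CTT (L) -> TTT (F) as the fixture convention.
#' Positions and flanks are fixed so classification is deterministic.
#'
#' @return An [amplicon_reference()] object whose `sequence` carries the L
#'   codon.
#' @export
synthetic_vgsc_reference <- function() {
  flank5 <- "AGCTTCATGATCGTGTTCCGGATCAACAAGCTGATCGGCGCCATGTACAACTTCGCCTT" # 60
  target <- paste0("CGTGGAACGTGC", "CTT", "GGTAC") # 20 nt, codon at 13-15
  flank3 <- "ACCGATCTGAAGGCAGTCCGTACGATCATCGAGTTCCTGGACAAGTTCTACGATCGGTAGCCTCTAACCA"
  amplicon_reference(
    sequence = paste0(flank5, target, substr(flank3, 1, 70)),
    target_start = 61L, target_end = 80L, codon_start = 73L,
    codon_L = "CTT", codon_F = "TTT"
  )
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# first occurrence of `pattern` in each of `subjects` allowing mismatches;
# returns start positions (NA where absent)
.anchor_starts <- function(pattern, subjects, max_mismatch) {
  hits <- Biostrings::vmatchPattern(pattern, subjects,
                                    max.mismatch = max_mismatch, fixed = TRUE)
  vapply(as.list(hits), function(ir) {
    if (length(ir) == 0L) NA_integer_ else Biostrings::start(ir)[1L]
  }, integer(1))
}

.classify_oriented <- function(seqs, ref, anchor_length, max_mismatch) {
  la <- substr(ref$sequence, ref$target_start - anchor_length,
               ref$target_start - 1L)
  ra <- substr(ref$sequence, ref$target_end + 1L,
               ref$target_end + anchor_length)
  subjects <- Biostrings::DNAStringSet(seqs)
  ls <- .anchor_starts(la, subjects, max_mismatch)
  rs <- .anchor_starts(ra, subjects, max_mismatch)
  win_start <- ls + anchor_length
  ok <- !is.na(ls) & !is.na(rs) & rs >= win_start
  width <- rs - win_start # observed target-window length
  expected <- ref$target_end - ref$target_start + 1L
  call <- rep(NA_character_, length(seqs))
  indel <- ok & width != expected
  call[indel] <- "NHEJ"
  intact <- ok & width == expected
  if (any(intact)) {
    off <- ref$codon_start - ref$target_start
    codon <- substr(seqs[intact], win_start[intact] + off,
                    win_start[intact] + off + 2L)
    call[intact][codon == ref$codon_L] <- "L"
    call[intact][codon == ref$codon_F] <- "F"
    # intact window, codon neither variant -> unclassified (stays NA)
  }
  call
}

#' Classify amplicon reads into L / F / NHEJ allele calls
#'
#' Locates the target-site window in each read by exact-flank anchoring
#' (fixed-length anchors immediately abutting the window; reverse-complement
#' orientation is tried when the forward anchors fail), then calls the read:
#' `L` or `F` if the window has its reference length and codon 1014 matches
#' the respective codon; `NHEJ` if the anchor spacing shows an indel inside
#' the window; otherwise unclassified. The procedure is deterministic.
#' Unclassified reads are reported alongside, never silently dropped:
#' reported frequencies are over classified reads only.
#'
#' @param reads Character vector of read sequences, a data frame with a
#'   `sequence` column (as from [generate_amplicon_reads()]), a
#'   `Biostrings::DNAStringSet`, or the path of a FASTA/FASTQ file (gzipped
#'   accepted).
#' @param ref An [amplicon_reference()].
#' @param max_mismatch Mismatches tolerated when matching each anchor
#'   (default 0: exact flanks).
#' @param anchor_length Anchor length in nt (default 15).
#' @return One-row tibble with counts `n_L`, `n_F`, `n_NHEJ`,
#'   `n_unclassified` and frequencies `freq_L`, `freq_F`, `freq_NHEJ`
#'   computed over classified reads. Attribute `calls` holds the per-read
#'   call vector.
#' @examples
#' ref <- synthetic_vgsc_reference()
#' reads <- generate_amplicon_reads(100, c(L = 0.6, F = 0.4, NHEJ = 0),
#'                                  ref = ref, seed = 1)
#' classify_amplicon_reads(reads, ref)
#' @export
classify_amplicon_reads <- function(reads, ref = synthetic_vgsc_reference(),
                                    max_mismatch = 0L, anchor_length = 15L) {
  stopifnot(inherits(ref, "amplicon_reference"),
            max_mismatch >= 0, anchor_length >= 6,
            ref$target_start - anchor_length >= 1,
            ref$target_end + anchor_length <= nchar(ref$sequence))
  seqs <- .read_sequences(reads)
  n <- length(seqs)
  if (n == 0L) {
    return(.allele_counts(character(0)))
  }
  parseable <- grepl("^[ACGTacgtNn]+$", seqs) & nchar(seqs) > 0
  if (any(!parseable)) {
    warning(sum(!parseable), " unreadable record(s) counted as unclassified",
            call. = FALSE)
  }
  call <- rep(NA_character_, n)
  idx <- which(parseable)
  if (length(idx)) {
    fw <- .classify_oriented(toupper(seqs[idx]), ref, anchor_length,
                             max_mismatch)
    miss <- is.na(fw)
    if (any(miss)) {
      fw[miss] <- .classify_oriented(.revcomp(toupper(seqs[idx][miss])), ref,
                                     anchor_length, max_mismatch)
    }
    call[idx] <- fw
  }
  .allele_counts(call)
}

.allele_counts <- function(call) {
  n_L <- sum(call == "L", na.rm = TRUE)
  n_F <- sum(call == "F", na.rm = TRUE)
  n_N <- sum(call == "NHEJ", na.rm = TRUE)
  n_U <- sum(is.na(call))
  cls <- n_L + n_F + n_N
  out <- tibble::tibble(
    n_L = n_L, n_F = n_F, n_NHEJ = n_N, n_unclassified = n_U,
    freq_L = if (cls > 0) n_L / cls else NA_real_,
    freq_F = if (cls > 0) n_F / cls else NA_real_,
    freq_NHEJ = if (cls > 0) n_N / cls else NA_real_
  )
  attr(out, "calls") <- call
  out
}

.read_sequences <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
    return(as.character(Biostrings::readDNAStringSet(reads, format = fmt)))
  }
  if (is.data.frame(reads)) {
    stopifnot("sequence" %in% names(reads))
    return(as.character(reads$sequence))
  }
  if (methods::is(reads, "DNAStringSet")) return(as.character(reads))
  if (is.character(reads)) return(reads)
  stop("unsupported `reads` input", call. = FALSE)
}

#' Generate synthetic amplicon reads from an allele mixture
#'
#' Draws read counts for the three allele classes from a multinomial with the
#' given mixture, builds each read from the reference amplicon (L and F reads
#' carry the respective codon; NHEJ reads carry one random indel inside the
#' target window), and optionally adds i.i.d. substitution errors. The ground
#' truth class is recorded in the read id.
#'
#' @param n_reads Number of reads.
#' @param mixture Numeric length-3 vector (`L`, `F`, `NHEJ`) summing to 1.
#' @param ref An [amplicon_reference()].
#' @param error_rate Per-base substitution error probability.
#' @param indel_range Integer range of NHEJ indel lengths (deletions and
#'   insertions drawn uniformly, sized to stay inside the target window).
#' @param seed Optional integer seed.
#' @return Tibble with columns `id` (carrying the true class), `truth`,
#'   `sequence`.
#' @export
generate_amplicon_reads <- function(n_reads, mixture,
                                    ref = synthetic_vgsc_reference(),
                                    error_rate = 0, indel_range = c(1L, 8L),
                                    seed = NULL) {
  stopifnot(n_reads >= 1, length(mixture) == 3L, all(mixture >= 0),
            abs(sum(mixture) - 1) < 1e-8,
            error_rate >= 0, error_rate < 1,
            length(indel_range) == 2L, indel_range[1L] >= 1,
            indel_range[2L] >= indel_range[1L])
  if (!is.null(seed)) set.seed(seed)
  counts <- as.integer(stats::rmultinom(1L, n_reads, mixture))
  truth <- sample(rep(c("L", "F", "NHEJ"), counts))
  base_L <- .with_codon(ref, ref$codon_L)
  base_F <- .with_codon(ref, ref$codon_F)
  seqs <- vapply(truth, function(tt) {
    switch(tt, L = base_L, F = base_F, NHEJ = .nhej_read(ref, indel_range))
  }, character(1), USE.NAMES = FALSE)
  if (error_rate > 0) seqs <- vapply(seqs, .add_errors, character(1),
                                     rate = error_rate, USE.NAMES = FALSE)
  tibble::tibble(
    id = sprintf("read_%05d|%s", seq_len(n_reads), truth),
    truth = truth,
    sequence = seqs
  )
}

.with_codon <- function(ref, codon) {
  s <- ref$sequence
  paste0(substr(s, 1L, ref$codon_start - 1L), codon,
         substr(s, ref$codon_start + 3L, nchar(s)))
}

# one random indel strictly inside the target window (anchors untouched);
# starts from the F (cleavable) allele, as NHEJ products arise from cut F
.nhej_read <- function(ref, indel_range) {
  s <- .with_codon(ref, ref$codon_F)
  win <- ref$target_end - ref$target_start + 1L
  len <- sample(seq.int(indel_range[1L], indel_range[2L]), 1L)
  if (stats::runif(1L) < 0.5 && len < win) { # deletion inside the window
    start <- ref$target_start + sample.int(win - len, 1L) - 1L
    paste0(substr(s, 1L, start - 1L), substr(s, start + len, nchar(s)))
  } else { # insertion at an interior window position
    at <- ref$target_start + sample.int(win - 1L, 1L) - 1L
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    paste0(substr(s, 1L, at), ins, substr(s, at + 1L, nchar(s)))
  }
}

.add_errors <- function(seq, rate) {
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble from [generate_amplicon_reads()] (columns `id`,
#'   `sequence`).
#' @param path Output path (`.gz` to compress).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads$sequence), function(w) strrep("I", w), character(1))
  )
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
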