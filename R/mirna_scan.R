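#' Define a miRNA seed for target-site scanning
#'
#' The seed is a prefix of the mature miRNA (5' end). A putative target
#' site is an 8-nt window of the mRNA whose antiparallel alignment against
#' the seed has at least `min_complementary` complementary pairs, where at
#' most `max_gu` G:U wobble pairs may count as complementary. DNA input
#' (T) is accepted and normalised to U; any other letter is rejected.
#'
#' @param mirna_sequence Mature miRNA sequence, 5' to 3' (RNA or DNA
#'   alphabet).
#' @param mirna_id Identifier used in reports.
#' @param seed_length Seed length in nucleotides (default 8).
#' @param min_complementary Minimum complementary pairs to declare a site
#'   (default 7, i.e. >= 7 of 8).
#' @param max_gu Maximum G:U pairs counted as complementary (default 1).
#' @param seed_offset 1-based start of the seed within the miRNA. Both
#'   position-1 and position-2 seed conventions exist; default 1.
#' @return A `seed_spec` object.
#' @examples
#' seed_spec("UGAUUGGUACGUCUGUGGGUAG", mirna_id = "miR-509-3p")
#' @export
seed_spec <- function(mirna_sequence, mirna_id = "miRNA", seed_length = 8L,
                      min_complementary = 7L, max_gu = 1L, seed_offset = 1L) {
  seq <- normalize_rna(mirna_sequence, what = "miRNA sequence")
  if (seed_offset < 1) stop("seed_offset must be >= 1")
  if (seed_offset + seed_length - 1 > nchar(seq)) {
    stop("seed (offset ", seed_offset, ", length ", seed_length,
         ") does not fit in a ", nchar(seq), "-nt miRNA")
  }
  if (min_complementary < 0 || min_complementary > seed_length) {
    stop("min_complementary must lie in [0, seed_length]")
  }
  if (max_gu < 0) stop("max_gu must be >= 0")
  structure(
    list(mirna_id = mirna_id, mirna_sequence = seq,
         seed_length = as.integer(seed_length),
         min_complementary = as.integer(min_complementary),
         max_gu = as.integer(max_gu), seed_offset = as.integer(seed_offset)),
    class = "seed_spec"
  )
}

#' @export
print.seed_spec <- function(x, ...) {
  cat("<seed_spec> ", x$mirna_id, ": seed ", seed_region(x),
      " (offset ", x$seed_offset, "), >=", x$min_complementary, "/",
      x$seed_length, " complementary, <=", x$max_gu, " G:U\n", sep = "")
  invisible(x)
}

# the seed nucleotides, 5'->3'
seed_region <- function(spec) {
  substr(spec$mirna_sequence, spec$seed_offset,
         spec$seed_offset + spec$seed_length - 1)
}

normalize_rna <- function(x, what = "sequence") {
  x <- chartr("acgut", "ACGUU", x)
  x <- chartr("T", "U", x)
  bad <- gsub("[ACGU]", "", x)
  if (any(nchar(bad) > 0)) {
    stop("invalid nucleotide(s) in ", what, ": ",
         paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]),
               collapse = ", "))
  }
  x
}

# exact antiparallel Watson-Crick complement (RNA), read 5'->3'
antiparallel_complement <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Classify one target/miRNA base pair
#'
#' Watson-Crick (`"WC"`) for A:U, U:A, G:C, C:G; wobble (`"GU"`) for G:U
#' and U:G; `"MISMATCH"` otherwise. Vectorised over both arguments.
#'
#' @param target_base,mirna_base Single nucleotides in A/C/G/U (T allowed,
#'   mapped to U).
#' @return Character vector in `c("WC", "GU", "MISMATCH")`.
#' @examples
#' pair_class("A", "U")  # WC
#' pair_class("G", "U")  # GU
#' @export
pair_class <- function(target_base, mirna_base) {
  t <- normalize_rna(target_base, "target base")
  m <- normalize_rna(mirna_base, "miRNA base")
  stopifnot(all(nchar(t) == 1), all(nchar(m) == 1))
  pair <- paste0(t, m)
  out <- rep("MISMATCH", length(pair))
  out[pair %in% c("AU", "UA", "GC", "CG")] <- "WC"
  out[pair %in% c("GU", "UG")] <- "GU"
  out
}

#' Scan one sequence for putative miRNA seed sites
#'
#' Slides a seed-length window along the target (5' to 3') and aligns each
#' window antiparallel against the seed: target position
#' `start + seed_length - 1 - j` pairs with seed position `j`. A window is
#' reported when the Watson-Crick pair count plus at most `max_gu`
#' creditable wobble pairs reaches `min_complementary`. Overlapping sites
#' are all reported; each window at most once.
#'
#' @param target Target sequence (character, RNA or DNA) or a length-1
#'   `Biostrings` XString/XStringSet element coerced with `as.character()`.
#' @param spec A [seed_spec()].
#' @param sequence_id Identifier recorded in the output.
#' @return A tibble with one row per site: `sequence_id`, `start`, `end`
#'   (0-based half-open), `window` (target subsequence 5'->3'), `n_wc`,
#'   `n_gu`, `n_mismatch`, sorted by `start`.
#' @export
scan_seed_sites <- function(target, spec, sequence_id = "seq") {
  stopifnot(inherits(spec, "seed_spec"))
  target <- normalize_rna(as.character(target), "target sequence")
  sl <- spec$seed_length
  n <- nchar(target)
  if (n < sl) stop("target (", n, " nt) is shorter than the seed (", sl, ")")

  seed_nt <- strsplit(seed_region(spec), "")[[1]]
  tgt <- strsplit(target, "")[[1]]
  n_win <- n - sl + 1L

  # pair classes per (window, seed position): window at 0-based start s
  # pairs target index s + sl - j against seed position j (1-based)
  wc <- matrix(FALSE, nrow = n_win, ncol = sl)
  gu <- matrix(FALSE, nrow = n_win, ncol = sl)
  starts <- seq_len(n_win)  # 1-based target index of window start
  for (j in seq_len(sl)) {
    tb <- tgt[starts + sl - j]
    pair <- paste0(tb, seed_nt[j])
    wc[, j] <- pair %in% c("AU", "UA", "GC", "CG")
    gu[, j] <- pair %in% c("GU", "UG")
  }
  n_wc <- rowSums(wc)
  n_gu <- rowSums(gu)
  score <- n_wc + pmin(n_gu, spec$max_gu)
  hit <- which(score >= spec$min_complementary)

  windows <- if (length(hit) > 0) {
    substring(target, hit, hit + sl - 1L)
  } else character(0)
  hit_wc <- as.integer(n_wc[hit])
  hit_gu <- as.integer(n_gu[hit])
  tibble::tibble(
    sequence_id = rep(sequence_id, length(hit)),
    start = as.integer(hit - 1L),
    end = as.integer(hit - 1L + sl),
    window = windows,
    n_wc = hit_wc,
    n_gu = hit_gu,
    n_mismatch = sl - hit_wc - hit_gu
  )
}

#' Scan every record of a FASTA file for seed sites
#'
#' Records shorter than the seed are skipped with a warning; scans never
#' cross record boundaries.
#'
#' @param path FASTA file path (DNA or RNA alphabet).
#' @param spec A [seed_spec()].
#' @return A tibble as in [scan_seed_sites()], one row per site across all
#'   records, with the record id in `sequence_id`.
#' @export
scan_fasta <- function(path, spec) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  short <- nchar(seqs) < spec$seed_length
  if (any(short)) {
    warning(sum(short), " record(s) shorter than the seed were skipped: ",
            paste(ids[short], collapse = ", "))
  }
  keep <- which(!short)
  purrr::map_dfr(keep, function(i) {
    scan_seed_sites(seqs[i], spec, sequence_id = ids[i])
  })
}
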