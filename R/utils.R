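# Internal helpers: deterministic string hashing, seed substreams, codon
# tables and reverse translation shared across modules.

# Large prime modulus; keeps every intermediate product below 2^53 so the
# hash is exact in double arithmetic and below 2^31 for use as a seed.
.hash_mod <- 1000000007

# Deterministic polynomial rolling hash of a character vector. `key` shifts
# the stream so independent consumers (mock predictor, per-patient seeds)
# decorrelate.
str_hash <- function(x, key = 0) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    h <- (5381 + key) %% .hash_mod
    for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% .hash_mod
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Named substream: a 32-bit-safe integer seed derived from a global seed and
# a label (e.g. patient id), stable across platforms.
derive_seed <- function(seed, label) {
  as.integer(str_hash(as.character(label), key = seed))
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# One fixed codon per amino acid (common human-preferred codons); used for
# deterministic reverse translation of construct proteins. No stop codons,
# so a reverse-translated ORF never truncates on re-translation.
.CODON_OF <- c(
  A = "GCC", R = "CGG", N = "AAC", D = "GAC", C = "TGC",
  Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
  L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCC",
  S = "AGC", T = "ACC", W = "TGG", Y = "TAC", V = "GTG"
)

.SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
.STOP_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]

# Translate a nucleotide string with the standard code; trailing partial
# codons are dropped. Returns the AA string including any '*' stops.
# Plain codon-table lookup: orders of magnitude cheaper than an XString
# round trip when called once per variant.
translate_nt <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# Deterministic reverse translation with the fixed codon table.
reverse_translate <- function(aa) {
  if (nchar(aa) == 0L) return("")
  res <- strsplit(aa, "")[[1]]
  bad <- setdiff(res, names(.CODON_OF))
  if (length(bad) > 0L) {
    abort(paste0("non-standard residue(s) in sequence: ",
                 paste(unique(bad), collapse = ", ")),
          class = "neovax_assembly_error")
  }
  paste(.CODON_OF[res], collapse = "")
}

# Run code under a derived seed without touching the caller's RNG state.
with_substream <- function(seed, label, code) {
  withr::with_seed(derive_seed(seed, label), code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
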