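# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")

.isCount <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

.isFraction <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# Evaluate `expr` under a private RNG state seeded with `seed`; the caller's
# global RNG stream is untouched, so generated objects are order-independent.
withLocalSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derived from (seed, index); kept below 2^31 - 1.
derivedSeed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

randomDna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Per-site substitution at probability `divergence`; a substituted base always
# changes, so the realised substitution count is Binomial(length, divergence).
mutateDna <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < divergence)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) sample(DNA_BASES[DNA_BASES != b], 1L),
                         character(1L), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "")
}
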