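## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded operations do not
#' perturb the global random stream. A NULL seed evaluates in place.
#' @noRd
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force seed initialisation so we can restore it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Validate a DNA string over {A,C,G,T,N}
#'
#' Returns the normalised (upper-case, U->T) string, or stops with the
#' 1-based position of the first offending character.
#' @noRd
normalizeDna <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- regexpr("[^ACGTN]", x)
  if (bad > 0L) {
    stop(sprintf("invalid residue '%s' at position %d in %s",
                 substr(x, bad, bad), bad, what), call. = FALSE)
  }
  x
}

## strand-aware reverse complement on plain character vectors
#' Reverse complement of a DNA string
#'
#' Validates the alphabet ({A,C,G,T,N}, case-insensitive, U accepted as T)
#' and returns the reverse complement. An involution: applying it twice is
#' the identity.
#'
#' @param x A character vector of DNA strings.
#' @return A character vector of reverse-complemented strings.
#' @examples
#' revComp("AAC")   # "GTT"
#' revComp("ACGT")  # "ACGT" (palindrome)
#' @export
revComp <- function(x) {
  vapply(x, function(s) {
    s <- normalizeDna(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Percent of a genome occupied by a number of bases
#'
#' Plain percentage used in the repeat and MTPT coverage reports:
#' 100 * bp / genome_len. Callers are expected to pass union (non
#' double-counted) base totals.
#'
#' @param bp Number of bases covered.
#' @param genome_len Genome length in nt.
#' @param digits Rounding for display; NULL for full precision.
#' @return Numeric percentage.
#' @examples
#' percentOfGenome(24681, 256961, digits = 2)
#' @export
percentOfGenome <- function(bp, genome_len, digits = NULL) {
  stopifnot(genome_len > 0, bp >= 0)
  p <- 100 * bp / genome_len
  if (!is.null(digits)) p <- round(p, digits)
  p
}

## sample a random DNA string at a given GC content
randomDna <- function(n, gc = 0.44) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## apply substitutions to a DNA string at per-base probability `rate`
mutateDna <- function(s, rate) {
  if (rate <= 0 || nchar(s) == 0L) return(s)
  v <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1),
                     character(1))
  }
  paste(v, collapse = "")
}

## integer encoding for fast comparison (N and anything odd -> NA)
dnaToInt <- function(s) {
  match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
}
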