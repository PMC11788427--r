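#' @importFrom stats rbinom rnorm rpois runif setNames quantile median sd cor.test
#' @importFrom utils head tail write.table read.table modifyList
#' @importFrom methods is
#' @import data.table
NULL

.datatable.aware <- TRUE

rs_log <- function(..., level = "INFO") {
  if (isTRUE(getOption("riboscope.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[riboscope %s] %s", level, paste0(...)))
}

#' Derive a stage seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds so each stochastic
#' stage is independently reproducible. The derivation is a fixed affine
#' map folded into the 32-bit signed integer range.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"simulate"`, `"train"`).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# reverse complement for plain character DNA (Biostrings used at IO
# boundaries; this avoids round-tripping tiny strings through XStringSet)
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

normalize_dna <- function(x) {
  chartr("Uu", "Tt", toupper(x))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

is_stop_codon <- function(codon) codon %in% STOP_CODONS

`%||%` <- function(a, b) if (is.null(a)) b else a
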