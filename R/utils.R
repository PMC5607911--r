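# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
sc_log <- function(fmt, ...) {
  message(sprintf(paste0("[shellcand] ", fmt), ...))
}

# wrap a stage so failures name the stage that produced them
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("%s stage: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# substitute a different random base at given positions of an integer-coded seq
other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

# check a scalar is a single finite number
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# integer gcd
gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}
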