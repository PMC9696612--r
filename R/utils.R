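# Shared low-level helpers: the 20-letter alphabet, integer encoding and
# the substitution noise model used by the simulator.

#' The 20 standard amino acids
#'
#' Alphabet used throughout: no ambiguity codes are emitted by the
#' simulator and profile matrices are defined over exactly these letters,
#' which keeps the exact p-value dynamic programming closed.
#' @export
AA_STANDARD20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Uniform residue background
#' @keywords internal
uniformBackground <- function() {
    stats::setNames(rep(1 / 20, 20), AA_STANDARD20)
}

encodeResidues <- function(x) {
    match(strsplit(x, "", fixed = TRUE)[[1L]], AA_STANDARD20)
}

decodeResidues <- function(code) {
    paste(AA_STANDARD20[code], collapse = "")
}

randomProtein <- function(n, background = NULL) {
    paste(sample(AA_STANDARD20, n, replace = TRUE, prob = background),
          collapse = "")
}

#' Per-residue substitution noise
#'
#' Each residue is, independently with probability `rate`, redrawn from the
#' background distribution (which may return the original residue, so the
#' expected identity at `rate = 1` with a uniform background is 5%).
#' @keywords internal
substituteResidues <- function(x, rate, background = NULL) {
    if (rate <= 0) return(x)
    chars <- strsplit(x, "", fixed = TRUE)[[1L]]
    hit <- stats::runif(length(chars)) < rate
    if (any(hit))
        chars[hit] <- sample(AA_STANDARD20, sum(hit), replace = TRUE,
                             prob = background)
    paste(chars, collapse = "")
}

# Evaluate expr with a temporary RNG seed, restoring the caller's stream.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
    expr
}

# Weighted tabulation of integer codes 1..20.
weightedResidueCounts <- function(code, w) {
    out <- numeric(20)
    t <- rowsum(w, code)
    out[as.integer(rownames(t))] <- t[, 1L]
    out
}
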