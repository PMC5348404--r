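# Shared internal helpers: seed fan-out, atomic masses, input checks.

# Standard atomic masses (Da), conventional values. Covers the elements the
# pose and compound machinery accepts; anything else raises an error.
ATOMIC_MASSES <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38,
  Se = 78.971, Br = 79.904, I = 126.904
)

atomic_mass <- function(element) {
  m <- ATOMIC_MASSES[element]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    abort(paste0("Unsupported element(s): ", paste(bad, collapse = ", ")))
  }
  unname(m)
}

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-task seeds, used so that
#' every gene, compound batch or simulation stage gets an independent,
#' reproducible stream. Multiplicative-congruential step kept inside 32-bit
#' integer range.
#'
#' @param master Integer master seed.
#' @param index Positive integer task index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  stopifnot(length(master) == 1, length(index) == 1, is.finite(master), is.finite(index))
  m <- 2147483629
  as.integer(((abs(as.numeric(master)) %% m) * 48271 + as.numeric(index) * 16807) %% m + 1)
}

check_positive_int <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 1 || x != floor(x)) {
    abort(paste0("`", name, "` must be a single positive integer"))
  }
  invisible(as.integer(x))
}
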