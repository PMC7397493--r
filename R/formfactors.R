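## Elastic electron scattering form factors, neutral atoms.
##
## Five-Gaussian parameterizations f(s) = sum_i a_i exp(-b_i s^2) with
## s = sin(theta)/lambda in 1/angstrom (Peng's tabulation for neutral
## atoms).  Covers the elements that occur in polyalanine models, protein
## templates and the common bound species (waters, Ca, S).

.electronFF <- local({
  tab <- rbind(
    H  = c(0.0349, 0.1201, 0.1970, 0.0573, 0.1195,
           0.5347, 3.5867, 12.3471, 18.9525, 38.6269),
    C  = c(0.0893, 0.2563, 0.7570, 1.0487, 0.3575,
           0.2465, 1.7100, 6.4094, 18.6113, 50.2523),
    N  = c(0.1022, 0.3219, 0.7982, 0.8197, 0.1715,
           0.2451, 1.7481, 6.1925, 17.3894, 48.1431),
    O  = c(0.0974, 0.2921, 0.6910, 0.6990, 0.2039,
           0.2067, 1.3815, 4.6943, 12.7105, 32.4726),
    S  = c(0.2497, 0.5628, 1.3899, 2.1865, 0.7715,
           0.2681, 1.6711, 7.0267, 19.5377, 50.3888),
    Ca = c(0.4054, 1.3880, 2.1602, 3.7532, 2.2063,
           0.3499, 3.0991, 11.9608, 53.9353, 142.3892)
  )
  colnames(tab) <- c(paste0("a", 1:5), paste0("b", 1:5))
  tab
})

#' Electron form-factor table
#'
#' @return matrix with one row per element and columns `a1..a5`, `b1..b5`.
#' @export
electronFormFactorTable <- function() .electronFF

#' Elastic electron scattering factor
#'
#' Evaluates the 5-Gaussian parameterization
#' \eqn{f(s) = \sum_i a_i e^{-b_i s^2}} for a neutral atom, with
#' \eqn{s = \sin\theta/\lambda = 1/(2d)} in 1/angstrom.
#'
#' @param element element symbol (e.g. "C"); case-normalized.
#' @param s scattering parameter(s) in 1/angstrom, `>= 0`.
#' @param table coefficient table, by default the built-in electron table.
#'   There is deliberately no fallback to X-ray factors.
#' @return scattering amplitude(s) in angstroms.
#' @examples
#' electronFormFactor("C", 0)      # sum of the a_i
#' electronFormFactor("O", 0.25)
#' @export
electronFormFactor <- function(element, s, table = electronFormFactorTable()) {
  el <- normalizeElement(element)
  if (!el %in% rownames(table)) {
    stop("no electron form factor for element '", element, "'", call. = FALSE)
  }
  stopifnot(all(s >= 0))
  co <- table[el, ]
  a <- co[1:5]; b <- co[6:10]
  vapply(s, function(si) sum(a * exp(-b * si^2)), numeric(1))
}

normalizeElement <- function(element) {
  el <- gsub("[^A-Za-z]", "", element)
  paste0(toupper(substring(el, 1, 1)), tolower(substring(el, 2)))
}

## coefficient arrays for the compiled direct summation
.ffCoefsFor <- function(elements, table = electronFormFactorTable()) {
  els <- vapply(elements, normalizeElement, character(1))
  miss <- setdiff(unique(els), rownames(table))
  if (length(miss)) {
    stop("no electron form factor for element(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- match(els, rownames(table))
  list(a = table[, 1:5, drop = FALSE], b = table[, 6:10, drop = FALSE],
       idx = idx)
}
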