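#' Water-holding capacity from centrifugation weights
#'
#' Percent of the sample mass not recovered as sediment after
#' centrifugation: `(w_sample - w_sediment) / w_sample * 100`.  A
#' `convention = "sediment"` switch reports the complementary sediment mass
#' fraction instead (`w_sediment / w_sample * 100`), the form some
#' laboratories call WHC; the two always sum to 100.
#'
#' @param w_sample Sample weight in g (> 0).
#' @param w_sediment Sediment weight in g, between 0 and `w_sample`.
#' @param convention `"supernatant_free"` (default) or `"sediment"`.
#' @return WHC in percent.
#' @export
whc_percent <- function(w_sample, w_sediment,
                        convention = c("supernatant_free", "sediment")) {
  convention <- match.arg(convention)
  if (any(w_sample <= 0)) stop("'w_sample' must be positive", call. = FALSE)
  if (any(w_sediment < 0) || any(w_sediment > w_sample))
    stop("'w_sediment' must lie in [0, w_sample]", call. = FALSE)
  if (convention == "sediment") return(w_sediment / w_sample * 100)
  (w_sample - w_sediment) / w_sample * 100
}

#' Syneresis (whey separation) from centrifugation weights
#'
#' `w_supernatant / w_sample * 100`.
#'
#' @param w_supernatant Supernatant weight in g, between 0 and `w_sample`.
#' @param w_sample Sample weight in g (> 0).
#' @return Syneresis in percent.
#' @export
syneresis_percent <- function(w_supernatant, w_sample) {
  if (any(w_sample <= 0)) stop("'w_sample' must be positive", call. = FALSE)
  if (any(w_supernatant < 0) || any(w_supernatant > w_sample))
    stop("'w_supernatant' must lie in [0, w_sample]", call. = FALSE)
  w_supernatant / w_sample * 100
}

#' DPPH radical-scavenging inhibition
#'
#' `(abs_control - abs_sample) / abs_control * 100`.  Negative values
#' (pro-oxidant readings) are passed through with a warning.
#'
#' @param abs_control Absorbance of the DPPH control (> 0).
#' @param abs_sample Absorbance of the sample reaction.
#' @return Percent inhibition.
#' @export
dpph_inhibition <- function(abs_control, abs_sample) {
  if (any(abs_control <= 0))
    stop("'abs_control' must be positive", call. = FALSE)
  out <- (abs_control - abs_sample) / abs_control * 100
  if (any(out < 0))
    warning("negative inhibition (sample absorbance exceeds control)",
            call. = FALSE)
  out
}

#' Anthocyanin content from tri-wavelength absorbances
#'
#' `(0.0821 * A534 - 0.00687 * A643 - 0.002426 * A661) * 5`, in
#' micromol/100 g.
#'
#' @param abs534,abs643,abs661 Absorbances at 534, 643 and 661 nm (>= 0).
#' @return Anthocyanin content in micromol/100 g.
#' @export
anthocyanin_umol <- function(abs534, abs643, abs661) {
  if (any(c(abs534, abs643, abs661) < 0))
    stop("absorbances must be non-negative", call. = FALSE)
  (0.0821 * abs534 - 0.00687 * abs643 - 0.002426 * abs661) * 5
}

#' Thiobarbituric-acid value from absorbance
#'
#' `7.8 * abs532`.  The output is reported unitless; in lipid-oxidation
#' work it is conventionally read as mg malondialdehyde per kg sample.
#'
#' @param abs532 Absorbance at 532 nm (>= 0).
#' @return TBA value.
#' @export
tba_value <- function(abs532) {
  if (any(abs532 < 0)) stop("'abs532' must be non-negative", call. = FALSE)
  7.8 * abs532
}

#' Free fatty acid value from titration
#'
#' `titre * normality * 56.1 / w_sample` (56.1 g/mol is the KOH equivalent
#' weight).
#'
#' @param titre KOH titre volume in mL (>= 0).
#' @param normality KOH normality (>= 0).
#' @param w_sample Sample weight in g (> 0).
#' @return FFA value (microgram-per-gram scale).
#' @export
ffa_value <- function(titre, normality, w_sample) {
  if (any(w_sample <= 0)) stop("'w_sample' must be positive", call. = FALSE)
  if (any(titre < 0) || any(normality < 0))
    stop("'titre' and 'normality' must be non-negative", call. = FALSE)
  titre * normality * 56.1 / w_sample
}
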