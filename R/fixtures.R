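## expected md5 checksums of the packaged study tables; load_fixture()
## verifies them so silent fixture corruption is caught at load time
.fixture_md5 <- c(
  day0_levels.csv = "ca63917c733938423325ea635ff79e69",
  design_runs.csv = "000e27cbf2de1d1098bf7ef82fcdb999",
  model_coefficients.csv = "4ae3fdb6d5a6bbb751cfa46c811b53db",
  model_stats.csv = "b31b8ce934207b6ce91e1280d2f032b2",
  optimum.csv = "d15a7c9b79e6a57dd63fd784f50461d3",
  optimum_amounts.csv = "028d0880333d4e78c4a2f9a05ec8c67d",
  rate_constants.csv = "0659cedff37350e6814d71b438a244ce",
  storage_series.csv = "30a318a4e89302b1317f5e90c063161a")

.fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "lassikin")
  if (!nzchar(path)) stop("fixture '", file, "' not installed", call. = FALSE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.fixture_md5[[file]])))
    stop("fixture '", file, "' failed its integrity check", call. = FALSE)
  path
}

#' The mixture region of the packaged beverage study
#'
#' Three components — microgreen juice (A), dahi (B) and water (C) — with
#' bounds 5–9.5, 60–64.5 and 15–19.5 percent and a fixed mixture total of
#' 84.5 percent (sugar and stabilizer are held constant outside the
#' mixture).
#'
#' @return A [mixture_design_spec()].
#' @export
lassi_design_spec <- function() {
  mixture_design_spec(components = c("juice", "dahi", "water"),
                      lower = c(5, 60, 15), upper = c(9.5, 64.5, 19.5),
                      total = 84.5)
}

#' The packaged 17-run D-optimal study design with measured responses
#'
#' One row per run with actual component percentages and the sixteen
#' measured sensory, physicochemical, biochemical and antioxidant
#' responses.  Two runs whose printed amounts were rounded to two decimals
#' (and so summed to 84.51) are stored de-rounded (61.875/16.875 and
#' 6.875/16.875) so every run sums exactly to the 84.5 mixture total.
#'
#' @return Data frame with 17 rows.
#' @export
lassi_design_runs <- function() {
  utils::read.csv(.fixture_path("design_runs.csv"))
}

#' Load all packaged study fixtures
#'
#' Reads and validates the packaged tables of the beverage study: the
#' 17-run design with all responses, the published special-cubic model
#' coefficients and their fit statistics, the six-index storage series at
#' 5/15/25 degrees Celsius, the published rate constants with R-squared and
#' zero-order half-lives, day-0 index levels, and the optimum formulation
#' with predicted and observed responses.  The storage-temperature grid is
#' stored as 5/15/25 degrees Celsius throughout (the methods-text
#' temperatures).  Every file is checksummed at load.
#'
#' @return A list with elements `spec`, `design`, `coefficients` (long
#'   data frame), `models` (named list of [scheffe_model()]), `model_stats`,
#'   `storage` (named list of [storage_series()]), `storage_table`,
#'   `rates`, `day0` (named vector), `optimum_amounts` (named vector) and
#'   `optimum` (Table of predicted/observed responses).
#' @examples
#' fx <- lassi_fixtures()
#' predict_response(fx$models$total_flavonoid_content,
#'                  to_pseudo(fx$optimum_amounts, fx$spec))
#' @export
lassi_fixtures <- function() {
  spec <- lassi_design_spec()
  design <- lassi_design_runs()
  coefs <- utils::read.csv(.fixture_path("model_coefficients.csv"))
  models <- lapply(split(coefs, factor(coefs$response,
                                       levels = unique(coefs$response))),
                   function(d) scheffe_model(d$coefficient,
                                             degree = "special_cubic",
                                             response = d$response[1L]))
  model_stats <- utils::read.csv(.fixture_path("model_stats.csv"))
  storage_table <- utils::read.csv(.fixture_path("storage_series.csv"))
  storage <- read_storage_csv(.fixture_path("storage_series.csv"))
  rates <- utils::read.csv(.fixture_path("rate_constants.csv"))
  day0_df <- utils::read.csv(.fixture_path("day0_levels.csv"))
  day0 <- stats::setNames(day0_df$c0, day0_df$index_name)
  amounts_df <- utils::read.csv(.fixture_path("optimum_amounts.csv"))
  optimum_amounts <- stats::setNames(amounts_df$percent,
                                     amounts_df$component)
  optimum <- utils::read.csv(.fixture_path("optimum.csv"))
  list(spec = spec, design = design, coefficients = coefs, models = models,
       model_stats = model_stats, storage = storage,
       storage_table = storage_table, rates = rates, day0 = day0,
       optimum_amounts = optimum_amounts, optimum = optimum)
}
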