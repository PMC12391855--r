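#' Published cohort marginals used for calibration
#'
#' Per-level counts of the analytical sample (N = 4196) of the Rotterdam
#' birth-cohort study the synthetic generator emulates, cross-tabulated
#' against timely (first visit at 14 weeks or earlier, n = 3417) versus late
#' (after 14 weeks, n = 779) antenatal care initiation. Counts are taken from
#' the study's published descriptive table of the non-imputed data; variables
#' were incompletely observed, so per-variable totals fall short of 4196 and
#' the shortfall defines the default missingness rates of
#' [default_params()]. Parity counts were not published.
#'
#' @return A tibble with columns `variable`, `level`, `total`, `timely`,
#'   `late`.
#' @export
#' @examples
#' # early pregnancy recognition: 2554 of 3126 respondents, i.e. 81.7%
#' calibration_counts() |> dplyr::filter(variable == "early_recognition")
calibration_counts <- function() {
  tibble::tribble(
    ~variable, ~level, ~total, ~timely, ~late,
    "age_group", "<20",    239,  140,  99,
    "age_group", "20-25",  769,  584, 185,
    "age_group", "25-30", 1142,  940, 202,
    "age_group", "30-35", 1506, 1319, 187,
    "age_group", ">=35",   490,  387, 103,
    "migration", "none",           1908, 1711, 197,
    "migration", "2nd_generation",  610,  498, 112,
    "migration", "1st_generation", 1348, 1007, 341,
    "relationship", "partner", 3196, 2725, 471,
    "relationship", "single",   598,  430, 168,
    "intention", "planned",              2454, 2139, 315,
    "intention", "unplanned_wanted",      638,  491, 147,
    "intention", "unplanned_ambivalent",  465,  324, 141,
    "mental_illness", "no",     1845, 1559, 286,
    "mental_illness", "ever",    770,  673,  97,
    "mental_illness", "recent",  365,  308,  57,
    "language", "sufficient",   2400, 2085, 315,
    "language", "reasonable",    728,  578, 150,
    "language", "insufficient",  391,  274, 117,
    "education", "high",    910,  815,  95,
    "education", "medium", 1892, 1605, 287,
    "education", "low",     977,  726, 251,
    "employment", "yes", 2174, 1935, 239,
    "employment", "no",   862,  641, 221,
    "income", "high",   1886, 1704, 182,
    "income", "medium",  598,  490, 108,
    "income", "low",     686,  492, 194,
    "housing", "own",    1626, 1466, 160,
    "housing", "rented", 1572, 1249, 323,
    "deprivation", "low",    1336, 1181, 155,
    "deprivation", "medium", 1367, 1134, 233,
    "deprivation", "high",   1445, 1058, 387,
    "iq", ">=85",  2001, 1759, 242,
    "iq", "70-85",  521,  405, 116,
    "iq", "<70",    153,  110,  43,
    "early_recognition", "no",   572,  410, 162,
    "early_recognition", "yes", 2554, 2180, 374,
    "regular_cycle", "irregular_or_unknown", 1836, 1408, 428,
    "regular_cycle", "regular",              2360, 2009, 351
  )
}

# sample-size constants of the published analytical sample
.calibration_n <- list(total = 4196L, timely = 3417L, late = 779L)
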