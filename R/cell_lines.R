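# Cell-line fixtures: HER1-3 expression profiles (molecules/cell).

#' Study cell-line expression profiles
#'
#' The four human-mammary-epithelial study profiles.  The parental line
#' expresses approximately 200,000 EGFR/HER1 molecules per cell and only
#' trace HER2/HER3; the derived lines add HER2 (24H), HER3 (B5) or both
#' (D20).  HER2/HER3 levels for the derived lines and the trace levels of
#' the parental line are package choices within the ranges the study
#' design implies (HER3-expressing cells cluster near 40,000 copies/cell;
#' overexpressed HER2 reaches several hundred thousand).
#'
#' @return A data.frame with columns `name`, `label`, `her1`, `her2`,
#'   `her3` (molecules/cell).
#' @export
her_cell_lines <- function() {
  data.frame(
    name = c("parental", "24H", "B5", "D20"),
    label = c("HER2-3-", "HER2+3-", "HER2-3+", "HER2+3+"),
    her1 = c(200000, 200000, 200000, 200000),
    her2 = c(2000, 600000, 2000, 600000),
    her3 = c(2000, 2000, 40000, 40000),
    stringsAsFactors = FALSE
  )
}

#' Look up or construct a cell-line profile
#'
#' @param name Name of a fixture line (see [her_cell_lines()]), or `NULL`
#'   when `her1`..`her3` are given directly.
#' @param her1,her2,her3 Expression levels in molecules/cell (>= 0).
#' @return A list with elements `name`, `her1`, `her2`, `her3`.
#' @export
her_profile <- function(name = NULL, her1 = NULL, her2 = NULL, her3 = NULL) {
  if (!is.null(name) && is.null(her1)) {
    cl <- her_cell_lines()
    i <- match(name, cl$name)
    if (is.na(i)) stop("unknown cell line: ", name, call. = FALSE)
    return(list(name = cl$name[i], her1 = cl$her1[i],
                her2 = cl$her2[i], her3 = cl$her3[i]))
  }
  vals <- c(her1 = her1, her2 = her2, her3 = her3)
  if (length(vals) != 3L || any(!is.finite(vals)) || any(vals < 0))
    stop("her1, her2, her3 must be nonnegative numbers", call. = FALSE)
  list(name = if (is.null(name)) "custom" else name,
       her1 = her1, her2 = her2, her3 = her3)
}

#' Illustrative cell-line panel (synthetic)
#'
#' A small synthetic panel of expression profiles spanning the ranges seen
#' across epithelial cell lines, for use with [her_panel_predict()].  The
#' `adrr_like` / `adrr_e2_like` pair shares EGFR and HER3 levels but
#' differs strongly in HER2, mirroring the comparison used to probe the
#' HER2 dependence of HER3 activation.  These are constructed fixtures,
#' not literature values.
#'
#' @return A data.frame like [her_cell_lines()].
#' @export
her_panel_fixture <- function() {
  data.frame(
    name = c("adrr_like", "adrr_e2_like", "egfr_high", "her2_amplified",
             "triple_low"),
    label = c("low HER2", "high HER2", "EGFR-driven", "HER2-amplified",
              "low all"),
    her1 = c(30000, 30000, 1e6, 50000, 5000),
    her2 = c(20000, 600000, 10000, 2e6, 5000),
    her3 = c(40000, 40000, 40000, 40000, 5000),
    stringsAsFactors = FALSE
  )
}
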