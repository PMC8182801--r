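#' Read cell-level data from a CIF file
#'
#' Minimal CIF reader for the metric-only pipeline: only the cell lengths and
#' angles, the ambient temperature and pressure and the conventional R-factor
#' are consumed; every other tag is ignored. Values with crystallographic
#' standard uncertainties in parentheses, e.g. `11.640(2)`, are stripped to
#' their central value.
#'
#' @param path Path to a CIF file containing a single data block.
#' @return A list with `cell` (a [unit_cell()]), `temperature_K`,
#'   `pressure_kPa` and `r_factor` (each `NA` when the tag is absent).
#' @export
read_cell_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    hit <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (length(hit) == 0) return(NA_real_)
    val <- sub(paste0("^\\s*", tag, "\\s+"), "", hit[1])
    val <- sub("\\(.*\\)", "", val)        # strip s.u. in parentheses
    val <- gsub("['\"]", "", trimws(val))
    suppressWarnings(as.numeric(val))
  }
  pars <- c(grab("_cell_length_a"), grab("_cell_length_b"),
            grab("_cell_length_c"), grab("_cell_angle_alpha"),
            grab("_cell_angle_beta"), grab("_cell_angle_gamma"))
  if (anyNA(pars)) stop("CIF file lacks a complete set of cell parameters: ", path)
  list(cell = unit_cell(pars[1], pars[2], pars[3], pars[4], pars[5], pars[6]),
       temperature_K = grab("_diffrn_ambient_temperature"),
       pressure_kPa = grab("_diffrn_ambient_pressure"),
       r_factor = grab("_refine_ls_R_factor_gt"))
}
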