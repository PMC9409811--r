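#' Physical properties of a tissue class
#'
#' Bundles the electrical and thermal parameters that the field and bioheat
#' solvers need for one tissue label: electrical conductivity at 100 kHz,
#' thermal conductivity, density, specific heat, blood perfusion rate,
#' arterial blood temperature and metabolic heat production.
#'
#' @param label_name Name of the tissue class (e.g. \code{"grey_matter"}).
#' @param sigma Electrical conductivity at 100 kHz, S/m. Must be > 0.
#' @param k Thermal conductivity, W/(m K). Must be > 0.
#' @param rho Mass density, kg/m^3. Must be > 0.
#' @param c Specific heat capacity, J/(kg K). Must be > 0.
#' @param omega_b Blood perfusion rate, 1/s (volumetric flow of blood per
#'   unit tissue volume). Must be >= 0; 0 disables the perfusion sink.
#' @param T_b Arterial blood temperature, degrees C.
#' @param q_met Metabolic heat production, W/m^3.
#'
#' @return A one-row \code{data.frame} with the given fields.
#' @seealso [brain_tissue_table()]
#' @export
tissue_properties <- function(label_name, sigma, k, rho, c,
                              omega_b = 0, T_b = 37, q_met = 0) {
  stopifnot(is.character(label_name), length(label_name) == 1L)
  if (!(sigma > 0)) stop("sigma must be > 0 (got ", sigma, ")")
  if (!(k > 0)) stop("k must be > 0 (got ", k, ")")
  if (!(rho > 0)) stop("rho must be > 0 (got ", rho, ")")
  if (!(c > 0)) stop("c must be > 0 (got ", c, ")")
  if (omega_b < 0) stop("omega_b must be >= 0 (got ", omega_b, ")")
  data.frame(label_name = label_name, sigma = sigma, k = k, rho = rho,
             c = c, omega_b = omega_b, T_b = T_b, q_met = q_met,
             stringsAsFactors = FALSE)
}

#' Default brain tissue property table
#'
#' Property table for the three tissue classes of the segmented head model:
#' grey matter, white matter and hippocampus. Electrical conductivities are
#' the 100 kHz values used throughout (grey 0.28 S/m, white 0.27 S/m); the
#' hippocampus is treated as grey matter. Thermal parameters are standard
#' brain-tissue literature values and are the main calibration surface of
#' the model: they can be overridden per label via \code{...}.
#'
#' Labels are integers: 1 = grey matter, 2 = white matter, 3 = hippocampus.
#'
#' @param ... Named overrides, one per label name, each a named list of
#'   fields to replace, e.g.
#'   \code{brain_tissue_table(grey_matter = list(omega_b = 0))}.
#'
#' @return A \code{data.frame} with one row per label (rownames are the
#'   label integers as character) and columns
#'   \code{label, label_name, sigma, k, rho, c, omega_b, T_b, q_met}.
#' @examples
#' brain_tissue_table()
#' brain_tissue_table(white_matter = list(sigma = 0.30))
#' @export
brain_tissue_table <- function(...) {
  tab <- rbind(
    cbind(label = 1L,
          tissue_properties("grey_matter", sigma = 0.28, k = 0.55,
                            rho = 1045, c = 3700, omega_b = 0.0067)),
    cbind(label = 2L,
          tissue_properties("white_matter", sigma = 0.27, k = 0.48,
                            rho = 1045, c = 3580, omega_b = 0.0021)),
    cbind(label = 3L,
          tissue_properties("hippocampus", sigma = 0.28, k = 0.55,
                            rho = 1045, c = 3700, omega_b = 0.0067))
  )
  rownames(tab) <- as.character(tab$label)
  overrides <- list(...)
  for (nm in names(overrides)) {
    i <- match(nm, tab$label_name)
    if (is.na(i)) stop("unknown tissue label name: ", nm)
    ov <- overrides[[nm]]
    bad <- setdiff(names(ov), names(tab))
    if (length(bad)) stop("unknown tissue property field(s): ",
                          paste(bad, collapse = ", "))
    for (f in names(ov)) tab[i, f] <- ov[[f]]
  }
  validate_tissue_table(tab)
  tab
}

validate_tissue_table <- function(tab) {
  need <- c("label", "label_name", "sigma", "k", "rho", "c",
            "omega_b", "T_b", "q_met")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("tissue table lacks column(s): ",
                            paste(missing, collapse = ", "))
  with(tab, {
    if (any(sigma <= 0)) stop("tissue table: sigma must be > 0")
    if (any(k <= 0)) stop("tissue table: k must be > 0")
    if (any(rho <= 0)) stop("tissue table: rho must be > 0")
    if (any(c <= 0)) stop("tissue table: c must be > 0")
    if (any(omega_b < 0)) stop("tissue table: omega_b must be >= 0")
  })
  if (anyDuplicated(tab$label)) stop("tissue table: duplicate labels")
  invisible(tab)
}

#' Blood properties used by the Pennes perfusion term
#'
#' Density and specific heat of arterial blood, used in the perfusion sink
#' rho_b c_b omega_b (T_b - T) of the Pennes bioheat equation.
#'
#' @return Named list with \code{rho_b} (kg/m^3) and \code{c_b} (J/(kg K)).
#' @export
blood_properties <- function() list(rho_b = 1050, c_b = 3617)
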