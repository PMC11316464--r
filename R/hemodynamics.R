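#' Foramen cross-sectional area from the minor diameter
#'
#' The nutrient foramen is approximated as a circle whose diameter is the
#' measured minor diameter — a conservative choice, since only the minor
#' axis is measured and the true opening is at least that wide.
#'
#' @param minor_diameter foramen minor diameter(s), mm. Must be >= 0.
#' @return area(s) in mm^2: `pi * (d/2)^2`.
#' @export
foramen_area <- function(minor_diameter) {
  if (any(minor_diameter < 0, na.rm = TRUE))
    stop("foramen diameter must be >= 0", call. = FALSE)
  pi * (minor_diameter / 2)^2
}

#' Effective arterial lumen radius from foramen area(s)
#'
#' The nutrient artery's lumen occupies about 20% of the foramen area on
#' average; the remainder is vein, nerve and connective tissue. When a femur
#' carries more than one foramen, the areas are summed first and the
#' occupancy scaling is applied to the total — two foramina are equivalent
#' to one foramen of the summed area, exactly.
#'
#' @param areas numeric vector of foramen areas, mm^2. An empty vector means
#'   "no foramen observed" and returns `NA_real_` (not zero): such specimens
#'   carry no flow information.
#' @param occupancy fraction of foramen area occupied by the arterial lumen;
#'   default 0.20.
#' @return lumen radius in mm: `sqrt(occupancy * sum(areas) / pi)`, or `NA`
#'   for an empty input.
#' @export
effective_lumen_radius <- function(areas, occupancy = 0.20) {
  stopifnot(is.numeric(occupancy), length(occupancy) == 1L)
  if (occupancy <= 0 || occupancy > 1)
    stop("occupancy must be in (0, 1]", call. = FALSE)
  if (length(areas) == 0L) return(NA_real_)
  if (any(areas < 0, na.rm = TRUE)) stop("areas must be >= 0", call. = FALSE)
  sqrt(occupancy * sum(areas) / pi)
}

#' Blood-flow rate through the nutrient artery
#'
#' Empirical curved polynomial relating lumen radius to volumetric flow,
#' calibrated on fluorescent-microsphere measurements in mammals:
#' \deqn{\log_{10}\dot{Q} = -0.20\,x^2 + 1.91\,x + 1.82, \quad x = \log_{10} r}
#' with `r` the lumen radius in mm and the result in cm^3 s^-1. The
#' polynomial is strictly increasing for `log10(r) < 4.775`, which covers
#' every physically possible artery.
#'
#' @param lumen_radius lumen radius (or radii), mm; must be > 0.
#' @return flow rate(s), cm^3 s^-1.
#' @seealso [inverse_qdot()] for the inverse on the increasing branch.
#' @export
qdot <- function(lumen_radius) {
  if (any(lumen_radius <= 0, na.rm = TRUE))
    stop("lumen radius must be > 0", call. = FALSE)
  x <- log10(lumen_radius)
  10^(-0.20 * x^2 + 1.91 * x + 1.82)
}

#' Lumen radius implied by a blood-flow rate
#'
#' Inverts the flow polynomial on its monotone-increasing branch: solves
#' `0.20 x^2 - 1.91 x + (y - 1.82) = 0` for `x = log10(r)` given
#' `y = log10(qdot)` and takes the root with `x < 4.775`.
#'
#' @param q flow rate(s), cm^3 s^-1; must be > 0 and below the polynomial's
#'   maximum (`10^6.380125`, far beyond any biological flow).
#' @return lumen radius (radii), mm.
#' @export
inverse_qdot <- function(q) {
  if (any(q <= 0, na.rm = TRUE)) stop("flow must be > 0", call. = FALSE)
  y <- log10(q)
  disc <- 1.91^2 - 4 * 0.20 * (y - 1.82)
  if (any(disc < 0, na.rm = TRUE))
    stop("flow exceeds the range of the polynomial's increasing branch",
         call. = FALSE)
  x <- (1.91 - sqrt(disc)) / (2 * 0.20)   # root below the vertex at 4.775
  10^x
}

#' Legacy blood-flow index Qi
#'
#' `Qi = r^4 / L`, the Poiseuille-motivated index of femoral blood flow used
#' in earlier foramen studies: flow through a tube scales with the fourth
#' power of the radius and inversely with its length. By convention `r` here
#' is the full foramen-equivalent radius (not the 20% lumen radius) and `L`
#' the femur total length.
#'
#' @param foramen_radius foramen radius, mm; > 0.
#' @param femur_length femur total length, mm; > 0.
#' @return index value(s), mm^3.
#' @export
qi_index <- function(foramen_radius, femur_length) {
  if (any(foramen_radius <= 0, na.rm = TRUE) ||
      any(femur_length <= 0, na.rm = TRUE))
    stop("radius and femur length must be > 0", call. = FALSE)
  foramen_radius^4 / femur_length
}

#' Read a specimen table
#'
#' Columns: `taxon`, `specimen_id`, `foramen_minor_diameters_mm` (one or
#' more diameters separated by `;`, empty for "no foramen observed"),
#' `femur_length_mm`, `adult` (logical).
#'
#' @param path CSV file path.
#' @return a data.frame with the diameter list parsed into a list column
#'   `diameters`.
#' @export
read_specimens <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "specimen_id", "foramen_minor_diameters_mm",
            "femur_length_mm", "adult")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("specimen table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$taxon <- trimws(df$taxon)
  df$adult <- as.logical(df$adult)
  df$diameters <- lapply(strsplit(as.character(df$foramen_minor_diameters_mm), ";",
                                  fixed = TRUE),
                         function(s) as.numeric(s[nzchar(trimws(s))]))
  df
}

#' Per-specimen flow estimates
#'
#' Computes, for each usable specimen (adult, >= 1 foramen), the summed
#' foramen area, lumen radius, flow rate and legacy index.
#'
#' @param specimens data.frame as returned by [read_specimens()], or any
#'   data.frame with `taxon`, `femur_length_mm`, `adult` and a list column
#'   `diameters` of mm diameters.
#' @param occupancy lumen occupancy fraction passed to
#'   [effective_lumen_radius()].
#' @return data.frame with one row per usable specimen: `taxon`,
#'   `specimen_id`, `foramen_area_mm2`, `lumen_radius_mm`, `qdot_cm3_s`, `qi`.
#' @export
specimen_flow <- function(specimens, occupancy = 0.20) {
  keep <- specimens$adult & vapply(specimens$diameters, length, 1L) > 0L
  sp <- specimens[keep, , drop = FALSE]
  area <- vapply(sp$diameters, function(d) sum(foramen_area(d)), 0)
  lumen <- sqrt(occupancy * area / pi)
  data.frame(
    taxon = sp$taxon,
    specimen_id = sp$specimen_id,
    foramen_area_mm2 = area,
    lumen_radius_mm = lumen,
    qdot_cm3_s = qdot(lumen),
    qi = qi_index(sqrt(area / pi), sp$femur_length_mm),
    stringsAsFactors = FALSE
  )
}

#' Aggregate specimen flow estimates to taxa
#'
#' Per-specimen flow rates are computed first and then averaged within
#' taxon. The default is the geometric mean — flow is analysed on the log10
#' scale downstream, and the geometric mean is the mean in that domain; an
#' arithmetic mean is available. Juvenile specimens and specimens with no
#' observed foramen are excluded before aggregation.
#'
#' @param specimens specimen data.frame (see [specimen_flow()]).
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @param occupancy lumen occupancy fraction.
#' @return data.frame with one row per taxon with at least one usable
#'   specimen: `taxon`, `n_specimens`, `foramen_area_mm2`, `lumen_radius_mm`,
#'   `qdot_cm3_s`, `qi`. Taxa with no usable specimen are absent (no
#'   estimate), not zero.
#' @export
aggregate_taxa <- function(specimens, method = c("geometric", "arithmetic"),
                           occupancy = 0.20) {
  method <- match.arg(method)
  per <- specimen_flow(specimens, occupancy = occupancy)
  if (nrow(per) == 0L)
    return(data.frame(taxon = character(), n_specimens = integer(),
                      foramen_area_mm2 = numeric(), lumen_radius_mm = numeric(),
                      qdot_cm3_s = numeric(), qi = numeric()))
  avg <- function(x) if (method == "geometric") exp(mean(log(x))) else mean(x)
  agg <- lapply(split(per, per$taxon), function(g) {
    data.frame(taxon = g$taxon[1L],
               n_specimens = nrow(g),
               foramen_area_mm2 = avg(g$foramen_area_mm2),
               lumen_radius_mm = avg(g$lumen_radius_mm),
               qdot_cm3_s = avg(g$qdot_cm3_s),
               qi = avg(g$qi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Mass-independent maximum metabolic rate
#'
#' Divides a whole-animal MMR by `Bm^exponent` to remove the allometric
#' size effect; the conventional exponent for MMR is 0.67.
#'
#' @param mmr_total whole-animal MMR, mL O2 h^-1; > 0.
#' @param bm body mass, g; > 0.
#' @param exponent allometric exponent, default 0.67.
#' @return mass-independent MMR, mL O2 h^-1 g^-0.67.
#' @export
mass_independent_mmr <- function(mmr_total, bm, exponent = 0.67) {
  if (any(mmr_total <= 0, na.rm = TRUE) || any(bm <= 0, na.rm = TRUE))
    stop("MMR and body mass must be > 0", call. = FALSE)
  mmr_total / bm^exponent
}
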