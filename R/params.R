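# Shipped parameter tables: threat attributes, land-cover suitability and
# sensitivity, plot index weights, and grade intervals. All overridable
# through load_params(); values are the published coefficients for the
# northwest-Yunnan Rhinopithecus bieti study system.

threat_codes <- c("village_I", "village_II", "village_III", "village_IV",
                  "village_V", "village_VI", "village_VII", "village_road",
                  "other_nonforest", "economic_forest", "cropland",
                  "artificial_construction")

#' Default threat factor attributes
#'
#' The twelve threat factors: villages split by development grade I-VII,
#' village roads, and four land-derived threats. `d_max_km` is the maximum
#' effective distance of the threat, `weight` its relative destructiveness,
#' `decay` the distance-decay shape.
#'
#' @return data.frame with columns `name`, `label`, `d_max_km`, `weight`,
#'   `decay`.
#' @export
default_threats <- function() {
  data.frame(
    name = threat_codes,
    label = c(paste("Village", c("I", "II", "III", "IV", "V", "VI", "VII")),
              "Village road", "Other non-forestry land", "Economic forest",
              "Cropland", "Artificial construction"),
    d_max_km = c(2, 2, 2, 2, 2, 2, 2, 4, 1, 1, 1, 3),
    weight = c(0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.7, 0.6, 0.7, 0.5, 0.8),
    decay = c(rep("exponential", 7), "linear", rep("exponential", 4)),
    stringsAsFactors = FALSE
  )
}

#' Land-cover classes and habitat suitability
#'
#' The 14 integer land-cover codes with habitat suitability H in \[0, 1\] for
#' the Yunnan snub-nosed monkey. Suitability takes one of five values
#' (1, 0.8, 0.6, 0.2, 0) matching the five habitat categories from optimal to
#' highly unfavorable.
#'
#' @return data.frame with columns `code`, `name`, `suitability`.
#' @export
lulc_classes <- function() {
  data.frame(
    code = 1:14,
    name = c("other non-forest land", "cold coniferous forest", "shrublands",
             "Armand pine and hemlock", "barren land", "broad-leaved forests",
             "cropland", "planted economic forests", "water body",
             "sclerophyllous evergreen broad-leaved forest", "fir-spruce forest",
             "warm coniferous forest", "coniferous broad-leaved mixed forest",
             "artificial construction"),
    suitability = c(0, 0.6, 0.8, 1, 0.2, 0.6, 0, 0, 0.2, 0.8, 1, 0.2, 1, 0),
    stringsAsFactors = FALSE
  )
}

#' Default sensitivity of land-cover classes to each threat
#'
#' 14 x 12 matrix: rows are land-cover codes 1-14, columns the twelve threat
#' factors in [default_threats()] order. Classes with zero habitat suitability
#' (codes 1, 7, 8, 14) have all-zero sensitivity.
#'
#' @return numeric matrix with rownames `1`..`14` and threat-name colnames.
#' @export
default_sensitivity <- function() {
  s <- rbind(
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),                       # 1
    c(0.7, 0.75, 0.8, 0.9, 0.9, 0.9, 0.9, 0.95, 0.4, 0.3, 0.4, 0.8), # 2
    c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.5, 0.3, 0.4, 0.8),  # 3
    c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.5, 0.4, 0.5, 0.9),  # 4
    c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.2, 0.1, 0.1, 0.2),  # 5
    c(0.6, 0.6, 0.6, 0.6, 0.7, 0.7, 0.8, 0.9, 0.4, 0.3, 0.4, 0.8),  # 6
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),                       # 7
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),                       # 8
    c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.3, 0.4, 0.2, 0.1, 0.1, 0.2),  # 9
    c(0.7, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.5, 0.3, 0.4, 0.8),  # 10
    c(0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.5, 0.4, 0.5, 0.9),  # 11
    c(0.3, 0.3, 0.3, 0.3, 0.4, 0.4, 0.4, 0.4, 0.2, 0.3, 0.1, 0.2),  # 12
    c(0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.85, 0.85, 0.5, 0.4, 0.5, 0.9), # 13
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)                        # 14
  )
  dimnames(s) <- list(as.character(1:14), threat_codes)
  s
}

#' Default plot ecological index weights
#'
#' Expert-assigned weights of the seven plot evaluation indices; they sum
#' to 1.
#'
#' @return named numeric vector of length 7.
#' @export
default_plot_weights <- function() {
  c(forest_naturalness = 0.19, community_structure = 0.18,
    tree_species_structure = 0.17, vegetation_coverage = 0.14,
    crown_density = 0.13, tree_height = 0.13, litter_depth = 0.06)
}

#' Full default parameter set
#'
#' All tunable parameters of the pipeline with their shipped defaults:
#' threat attributes, land-cover suitability and sensitivity, plot index
#' weights, the composite-score grade breaks (village grades I-VII), the plot
#' ecological grade breaks, the habitat-quality grade breaks, the
#' half-saturation constant `k`, the quality exponent `z`, kernel-density
#' bandwidth (`NULL` = grid extent / 30), hot-spot aggregation block size
#' (pixels), and Moran permutation count.
#'
#' @return named list of parameter tables and scalars.
#' @export
default_params <- function() {
  list(
    threats = default_threats(),
    suitability = stats::setNames(lulc_classes()$suitability,
                                  as.character(lulc_classes()$code)),
    sensitivity = default_sensitivity(),
    plot_weights = default_plot_weights(),
    village_grade_breaks = c(-0.5, 0, 0.5, 1, 1.5, 2),
    plot_grade_breaks = c(1.4, 1.8, 2.2),
    quality_grade_breaks = c(0.2, 0.4, 0.6, 0.8),
    k = 0.5,
    z = 2.5,
    bandwidth = NULL,
    unit_size = 5L,
    permutations = 999L
  )
}

#' Load and validate pipeline parameters
#'
#' Reads a JSON parameter file and merges it over [default_params()]. The
#' file may override any scalar (`k`, `z`, `bandwidth`, `unit_size`,
#' `permutations`), replace `plot_weights` or grade-break vectors, and patch
#' individual entries of the threat table (`threats` keyed by threat name),
#' the suitability vector (keyed by land-cover code) and the sensitivity
#' matrix (keyed by code, then threat name). An empty or missing file yields
#' the shipped defaults.
#'
#' @param path path to a JSON file, or `NULL` for pure defaults.
#' @return validated parameter list as in [default_params()].
#' @export
load_params <- function(path = NULL) {
  p <- default_params()
  if (!is.null(path)) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    ov <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt, simplifyVector = TRUE)
          else list()
    p <- apply_param_overrides(p, ov)
  }
  validate_params(p)
  p
}

apply_param_overrides <- function(p, ov) {
  if (length(ov) == 0) return(p)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(ov)) {
    val <- ov[[nm]]
    if (nm == "threats" && is.list(val) && !is.data.frame(val)) {
      for (tn in names(val)) {
        i <- match(tn, p$threats$name)
        if (is.na(i)) stop("threats: unknown threat name '", tn, "'")
        for (f in names(val[[tn]])) {
          if (!f %in% c("d_max_km", "weight", "decay"))
            stop("threats$", tn, ": unknown field '", f, "'")
          p$threats[[f]][i] <- val[[tn]][[f]]
        }
      }
    } else if (nm == "suitability" && is.list(val)) {
      for (cd in names(val)) {
        if (!cd %in% names(p$suitability))
          stop("suitability: unknown land-cover code '", cd, "'")
        p$suitability[[cd]] <- val[[cd]]
      }
    } else if (nm == "sensitivity" && is.list(val)) {
      for (cd in names(val)) {
        if (!cd %in% rownames(p$sensitivity))
          stop("sensitivity: unknown land-cover code '", cd, "'")
        for (tn in names(val[[cd]])) {
          if (!tn %in% colnames(p$sensitivity))
            stop("sensitivity$", cd, ": unknown threat name '", tn, "'")
          p$sensitivity[cd, tn] <- val[[cd]][[tn]]
        }
      }
    } else if (nm == "plot_weights" && !is.null(names(val))) {
      bad <- setdiff(names(val), names(p$plot_weights))
      if (length(bad))
        stop("plot_weights: unknown index name(s): ", paste(bad, collapse = ", "))
      p$plot_weights[names(val)] <- unlist(val)
    } else {
      p[[nm]] <- if (nm == "unit_size" || nm == "permutations")
        as.integer(val) else unlist(val)
    }
  }
  p
}

validate_params <- function(p) {
  th <- p$threats
  if (any(th$weight <= 0 | th$weight > 1))
    stop("threats$weight: all weights must be in (0, 1]")
  if (any(th$d_max_km <= 0))
    stop("threats$d_max_km: all distances must be positive")
  if (!all(th$decay %in% c("exponential", "linear")))
    stop("threats$decay: must be 'exponential' or 'linear'")
  if (any(p$suitability < 0 | p$suitability > 1))
    stop("suitability: values must be in [0, 1]")
  if (any(p$sensitivity < 0 | p$sensitivity > 1))
    stop("sensitivity: values must be in [0, 1]")
  if (any(p$plot_weights <= 0))
    stop("plot_weights: weights must be positive")
  if (abs(sum(p$plot_weights) - 1) > 1e-9)
    stop("plot_weights: weights must sum to 1")
  for (nm in c("village_grade_breaks", "plot_grade_breaks",
               "quality_grade_breaks")) {
    if (is.unsorted(p[[nm]], strictly = TRUE))
      stop(nm, ": breaks must be strictly increasing")
  }
  if (!is.numeric(p$k) || p$k <= 0) stop("k: must be positive")
  if (!is.numeric(p$z) || p$z <= 0) stop("z: must be positive")
  if (!is.null(p$bandwidth) && p$bandwidth <= 0)
    stop("bandwidth: must be positive or NULL")
  if (p$unit_size < 1) stop("unit_size: must be >= 1")
  if (p$permutations < 1) stop("permutations: must be >= 1")
  invisible(p)
}
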