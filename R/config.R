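#' Default run configuration
#'
#' Returns the nested list of tunable parameters used across the pipeline.
#' Any subset can be overridden by passing a partial list to the stage
#' functions or by [load_config()].
#'
#' Blocks:
#' \describe{
#'   \item{pm}{Perona-Malik: `iterations` (10), `kappa` (0.1 intensity
#'     units), `step` (0.2, explicit-scheme stable), `conductance`
#'     ("exponential").}
#'   \item{meanshift}{`bandwidth` (0.1 intensity units), `max_iter` (100),
#'     `tol` (1e-6).}
#'   \item{hadamard}{`eps` (1e-6) denominator stabilizer.}
#'   \item{drtb}{`level_grid` (0.01..0.99 step 0.01), `n_bins` (30
#'     equal-width histogram bins over the observed edge-length range;
#'     distances are expressed in bin units, making the fitted sigma
#'     scale-free and comparable across magnifications), `bin_width`
#'     (NULL; set to a pixel width to use fixed-width bins instead, with
#'     `sigma_grid` then read in pixels), `sigma_grid`
#'     (0.5..30 step 0.1, in bin units), `connectivity` (8),
#'     `mad_b` (1.4826), `mad_cutoff` (3), `min_area` (9 px speckle guard),
#'     `invert` (FALSE; scan `1 - F` for dark-stomata imagery),
#'     `unique_edges` (FALSE; drop duplicated shared-edge distances),
#'     `drop_border` (FALSE; discard regions touching the frame),
#'     `max_points` (2000; levels with more usable centroids are marked
#'     invalid rather than tessellated — counts far beyond the largest
#'     observed stomatal populations imply a threshold slicing noise, not
#'     stomata).}
#'   \item{evaluation}{`radius` (30 px center-matching threshold).}
#' }
#'
#' @param ... Named top-level blocks overriding the defaults, e.g.
#'   `drtb_config(drtb = list(bin_width = 2))`.
#' @return Nested configuration list.
#' @export
drtb_config <- function(...) {
  cfg <- list(
    pm = list(iterations = 10L, kappa = 0.1, step = 0.2,
              conductance = "exponential"),
    meanshift = list(bandwidth = 0.1, max_iter = 100L, tol = 1e-6),
    hadamard = list(eps = 1e-6),
    drtb = list(
      level_grid = seq(0.01, 0.99, by = 0.01),
      sigma_grid = seq(0.5, 30, by = 0.1),
      n_bins = 30L,
      bin_width = NULL,
      connectivity = 8L,
      mad_b = 1.4826,
      mad_cutoff = 3,
      min_area = 9L,
      invert = FALSE,
      unique_edges = FALSE,
      drop_border = FALSE,
      max_points = 2000L
    ),
    evaluation = list(radius = 30)
  )
  override <- list(...)
  merge_config(cfg, override)
}

#' Read a YAML/JSON configuration file and merge it over the defaults
#'
#' @param path Path to a YAML (or JSON; YAML is a superset) file holding any
#'   subset of the blocks documented in [drtb_config()].
#' @return Full configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_config(drtb_config(), user)
}

merge_config <- function(base, override) {
  if (length(override) == 0L) return(base)
  if (is.null(names(override)) || any(names(override) == "")) {
    stop("configuration overrides must be named")
  }
  bad <- setdiff(names(override), names(base))
  if (length(bad)) stop("unknown configuration entries: ",
                        paste(bad, collapse = ", "))
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- utils::modifyList(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
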