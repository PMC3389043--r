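# Microscopy counts -> biovolume -> carbon biomass. Cell volumes come from
# the nearest geometric solid; carbon conversions are group-specific: a
# constant 0.190 pg C um^-3 for ciliates, the 0.760 V^0.819 power law for
# dinoflagellates, and configurable size-dependent power laws for
# phytoplankton groups.

SHAPE_DIMS <- c(sphere = 1L, prolate_spheroid = 2L, cylinder = 2L,
                cone = 2L, cylinder_two_half_spheres = 2L)

shape_dim_count <- function(shape) {
  if (!shape %in% names(SHAPE_DIMS)) {
    stop("unknown shape: '", shape, "' (registered: ",
         paste(names(SHAPE_DIMS), collapse = ", "), ")")
  }
  SHAPE_DIMS[[shape]]
}

#' Cell biovolume from linear dimensions
#'
#' Standard solid-geometry formulas, dimensions in micrometres:
#' sphere `pi d^3 / 6` (dims: diameter); prolate spheroid `pi L w^2 / 6`
#' (length, width); cylinder `pi w^2 L / 4`; cone `pi w^2 L / 12`;
#' cylinder with two half-sphere caps `pi w^2 (L - w) / 4 + pi w^3 / 6`
#' (L is the total length including caps).
#'
#' @param shape registered shape name.
#' @param dims numeric vector of dimensions (um); the count must match the
#'   shape.
#' @return volume in cubic micrometres.
#' @examples
#' biovolume("sphere", 10)        # 523.60
#' biovolume("cylinder", c(10, 2)) # 31.416
#' @export
biovolume <- function(shape, dims) {
  nd <- shape_dim_count(shape)
  if (length(dims) != nd || any(!is.finite(dims)) || any(dims <= 0)) {
    stop("shape '", shape, "' needs ", nd, " positive dimension(s)")
  }
  switch(shape,
         sphere = pi * dims[1]^3 / 6,
         prolate_spheroid = pi * dims[1] * dims[2]^2 / 6,
         cylinder = pi * dims[2]^2 * dims[1] / 4,
         cone = pi * dims[2]^2 * dims[1] / 12,
         cylinder_two_half_spheres = {
           l <- dims[1]; w <- dims[2]
           if (l < w) stop("total length must be >= width for capped ",
                           "cylinders")
           pi * w^2 * (l - w) / 4 + pi * w^3 / 6
         })
}

#' Carbon content conversions
#'
#' `ciliate_carbon()` applies the constant factor 190 fg C per cubic
#' micrometre (0.190 pg C um^-3). `dino_carbon()` applies the
#' dinoflagellate power law `0.760 V^0.819` pg C. `phyto_carbon()` is the
#' generic size-dependent power law `a V^b` pg C used for phytoplankton
#' groups; the usual coefficients are 0.288/0.811 for diatoms and
#' 0.216/0.939 for non-diatom protists (see [default_allometry()]).
#'
#' @param volume cell biovolume in cubic micrometres.
#' @param a,b power-law coefficients (`a > 0`, `b > 0`).
#' @return carbon content in pg C per cell.
#' @export
ciliate_carbon <- function(volume) {
  if (any(volume < 0)) stop("volume must be non-negative")
  0.190 * volume
}

#' @rdname ciliate_carbon
#' @export
dino_carbon <- function(volume) {
  if (any(volume <= 0)) stop("volume must be positive")
  0.760 * volume^0.819
}

#' @rdname ciliate_carbon
#' @export
phyto_carbon <- function(volume, a, b) {
  if (any(volume <= 0)) stop("volume must be positive")
  if (a <= 0 || b <= 0) stop("allometry coefficients must be positive")
  a * volume^b
}

#' Default carbon allometry configuration
#'
#' Per-group conversion rules: a `factor` entry is multiplied by volume
#' (pg C = factor x V); an `a`/`b` entry is the power law pg C = a V^b.
#' Diatoms and non-diatom protists carry the standard size-dependent
#' coefficients; *Phaeocystis* colony carbon is pluggable and defaults to
#' the generic non-diatom law; heterotrophic nanoflagellates use the same
#' generic law unless overridden.
#'
#' @return a named list, one entry per plankton group.
#' @export
default_allometry <- function() {
  list(ciliate = list(factor = 0.190),
       dinoflagellate = list(a = 0.760, b = 0.819),
       diatom = list(a = 0.288, b = 0.811),
       nanoflagellate = list(a = 0.216, b = 0.939),
       phaeocystis_colony = list(a = 0.216, b = 0.939))
}

cell_carbon <- function(group, volume, allometry) {
  conv <- allometry[[group]]
  if (is.null(conv)) stop("no carbon conversion registered for group '",
                          group, "'")
  if (!is.null(conv$factor)) conv$factor * volume
  else phyto_carbon(volume, conv$a, conv$b)
}

#' Community carbon biomass from a microscopy table
#'
#' Converts each taxon-date row into biovolume (um^3 cell^-1), cell carbon
#' (pg C cell^-1) and biomass (`abundance x carbon x 1e-6` ug C L^-1), and
#' aggregates per-group and survey-category stocks. Categories follow the
#' usual bloom-survey reporting: autotrophs and mixotrophs form the
#' phytoplankton stock; heterotrophic ciliates and dinoflagellates form
#' the microzooplankton stock; remaining heterotrophs (nanoflagellates)
#' are nanoheterotrophs.
#'
#' @param counts microscopy table as produced by
#'   [generate_microscopy_table()].
#' @param allometry allometry configuration, see [default_allometry()].
#' @return a list with `records` (per taxon-date biomass table), `stocks`
#'   (per group-date ug C L^-1), `category_stocks` (per category-date) and
#'   `totals` (per date grand totals).
#' @export
community_biomass <- function(counts, allometry = default_allometry()) {
  if (nrow(counts) == 0L) {
    empty <- data.frame(group = character(), date = character(),
                        stock_ugC_per_L = numeric())
    return(list(records = data.frame(), stocks = empty,
                category_stocks = empty, totals = empty[-1]))
  }
  vol <- vapply(seq_len(nrow(counts)), function(i) {
    dims <- c(counts$dim1_um[i], counts$dim2_um[i])
    biovolume(counts$shape[i], dims[!is.na(dims)])
  }, numeric(1))
  carbon <- vapply(seq_len(nrow(counts)), function(i) {
    cell_carbon(counts$group[i], vol[i], allometry)
  }, numeric(1))
  records <- data.frame(
    taxon = counts$taxon, group = counts$group, trophic = counts$trophic,
    date = counts$date,
    abundance_cells_per_L = counts$abundance_cells_per_L,
    biovolume_um3 = vol, carbon_pgC_per_cell = carbon,
    biomass_ugC_per_L = counts$abundance_cells_per_L * carbon * 1e-6,
    stringsAsFactors = FALSE)
  records$category <- ifelse(
    records$trophic %in% c("auto", "mixo"), "phytoplankton",
    ifelse(records$group %in% c("ciliate", "dinoflagellate"),
           "microzooplankton", "nanoheterotrophs"))
  agg <- function(by) {
    out <- stats::aggregate(records$biomass_ugC_per_L,
                            by = c(by, list(date = records$date)), sum)
    names(out)[ncol(out)] <- "stock_ugC_per_L"
    out
  }
  stocks <- agg(list(group = records$group))
  cat_stocks <- agg(list(category = records$category))
  totals <- stats::aggregate(records$biomass_ugC_per_L,
                             by = list(date = records$date), sum)
  names(totals)[2] <- "stock_ugC_per_L"
  list(records = records, stocks = stocks, category_stocks = cat_stocks,
       totals = totals)
}

#' Survey fold changes of biomass stocks
#'
#' For each group (or category), the minimum and maximum stock over the
#' survey dates, their ratio, and the ratio rounded to the nearest integer
#' - the "n-fold increase" figure of bloom surveys. Groups with a zero
#' stock on some date get an undefined (NA) ratio.
#'
#' @param stocks a `data.frame` with columns naming the grouping (first
#'   column), `date` and `stock_ugC_per_L`.
#' @return a `data.frame` with `group`, `min`, `max`, `ratio`,
#'   `rounded_ratio`.
#' @examples
#' s <- data.frame(group = "phyto", date = c("mar", "apr"),
#'                 stock_ugC_per_L = c(42.6, 1439.1))
#' fold_change_summary(s)  # ratio 33.78, rounded 34
#' @export
fold_change_summary <- function(stocks) {
  grp_col <- names(stocks)[1]
  if (!all(c("date", "stock_ugC_per_L") %in% names(stocks))) {
    stop("stocks must have 'date' and 'stock_ugC_per_L' columns")
  }
  out <- lapply(split(stocks, stocks[[grp_col]]), function(s) {
    if (nrow(s) < 2) stop("need stocks for at least 2 dates per group")
    lo <- min(s$stock_ugC_per_L)
    hi <- max(s$stock_ugC_per_L)
    ratio <- if (lo <= 0) NA_real_ else hi / lo
    data.frame(group = s[[grp_col]][1], min = lo, max = hi, ratio = ratio,
               rounded_ratio = if (is.na(ratio)) NA_real_ else round(ratio),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
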