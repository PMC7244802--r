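field_required_cols <- c("genotype_id", "watershed", "band", "lat", "lon",
                         "elevation", "DBH", "leaf_area", "leaf_mass", "SLA")
garden_required_cols <- c("genotype_id", "replicate_id", "growth_diameter",
                          "leaf_area", "leaf_mass", "SLA")

read_trait_table <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) stop(what, ": no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  for (cc in numeric_cols) {
    raw <- df[[cc]]
    if (is.character(raw)) {
      conv <- suppressWarnings(as.numeric(raw))
      bad <- which(!is.na(raw) & is.na(conv))
      if (length(bad))
        stop(what, ": non-numeric value in column '", cc, "' at row ",
             bad[1L], ": '", raw[bad[1L]], "'")
      df[[cc]] <- conv
    }
  }
  df
}

#' Read field and common-garden trait tables
#'
#' CSV readers with schema validation: missing required columns raise an
#' error naming the column, non-numeric trait cells raise an error with the
#' row index, and `NA` cells are preserved as missing (never zero-filled).
#'
#' Field columns: `genotype_id, watershed, band, lat, lon, elevation, DBH`
#' (cm), `leaf_area` (cm^2, mean of five leaves), `leaf_mass` (g), `SLA`
#' (cm^2/g). Garden columns: `genotype_id, replicate_id, growth_diameter`
#' (mm, diameter of annual shoot growth), `leaf_area, leaf_mass, SLA`.
#'
#' @param path CSV file path.
#' @return data.frame of typed records.
#' @export
read_field_table <- function(path) {
  read_trait_table(path, field_required_cols,
                   c("lat", "lon", "elevation", "DBH", "leaf_area",
                     "leaf_mass", "SLA"), "read_field_table")
}

#' @rdname read_field_table
#' @export
read_garden_table <- function(path) {
  read_trait_table(path, garden_required_cols,
                   c("growth_diameter", "leaf_area", "leaf_mass", "SLA"),
                   "read_garden_table")
}

#' Keep one record per clone
#'
#' Clonal duplicates (identical `genotype_id`) are reduced to a single
#' record, keeping the first occurrence in file order.
#'
#' @param records data.frame with a `genotype_id` column.
#' @return data.frame with one row per genotype.
#' @export
dedup_clones <- function(records) {
  if (!"genotype_id" %in% names(records))
    stop("dedup_clones: records lack genotype_id")
  out <- records[!duplicated(records$genotype_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate records to site means
#'
#' Builds the regression unit of the analysis: one row per (watershed,
#' band) with mean trait values and site climate. Field traits are averaged
#' directly over genotypes; garden traits are averaged in two stages
#' (replicates to genotype, genotypes to site) so unequal replicate counts
#' do not weight genotypes unequally. Means use only non-missing values and
#' the contributing genotype count is stored. Sites with no contributing
#' records are dropped with a warning.
#'
#' @param field field records (see [read_field_table()]); must map to known
#'   sites via `watershed` + `band`.
#' @param garden optional garden records; linked to sites through the field
#'   table's `genotype_id`.
#' @param site_climate optional per-site climate table (`watershed`, `band`,
#'   plus any subset of [envirem_variables()]).
#' @return data.frame with one row per site: `watershed`, `band`,
#'   `n_field`, field trait means (`DBH`, `leaf_area`, `leaf_mass`, `SLA`),
#'   garden trait means prefixed `garden_`, and climate columns.
#' @export
site_means <- function(field, garden = NULL, site_climate = NULL) {
  need <- c("watershed", "band")
  if (!all(need %in% names(field)))
    stop("site_means: field records need watershed and band columns")
  key <- interaction(field$watershed, field$band, drop = TRUE, sep = "|")
  traits <- intersect(field_traits(), names(field))
  agg <- function(v, k) tapply(v, k, function(z) {
    z <- z[!is.na(z)]
    if (length(z)) mean(z) else NA_real_
  })
  out <- data.frame(watershed = vapply(strsplit(levels(key), "|",
                                                fixed = TRUE), `[`, "", 1L),
                    band = vapply(strsplit(levels(key), "|", fixed = TRUE),
                                  `[`, "", 2L))
  out$n_field <- as.integer(table(key))
  for (tr in traits) out[[tr]] <- as.vector(agg(field[[tr]], key))
  if (!is.null(garden)) {
    gtraits <- intersect(c("growth_diameter", "leaf_area", "leaf_mass",
                           "SLA"), names(garden))
    gsite <- field$genotype_id
    site_of <- stats::setNames(as.character(key), field$genotype_id)
    unknown <- setdiff(garden$genotype_id, names(site_of))
    if (length(unknown))
      stop("site_means: garden genotype(s) absent from field table: ",
           paste(utils::head(unknown, 3L), collapse = ", "))
    for (tr in gtraits) {
      # replicates -> genotype means -> site means
      gmean <- tapply(garden[[tr]], garden$genotype_id,
                      function(z) mean(z, na.rm = TRUE))
      sk <- factor(site_of[names(gmean)], levels = levels(key))
      out[[paste0("garden_", tr)]] <- as.vector(agg(as.vector(gmean), sk))
    }
    out$n_garden_genotypes <- as.integer(table(
      factor(site_of[unique(garden$genotype_id)], levels = levels(key))))
  }
  if (!is.null(site_climate)) {
    if (!all(need %in% names(site_climate)))
      stop("site_means: site_climate needs watershed and band columns")
    cvars <- intersect(envirem_variables(), names(site_climate))
    m <- match(paste(out$watershed, out$band),
               paste(site_climate$watershed, site_climate$band))
    for (cv in cvars) out[[cv]] <- site_climate[[cv]][m]
  }
  empty <- out$n_field == 0L
  if (any(empty)) {
    warning("site_means: dropping ", sum(empty),
            " site(s) with no contributing records")
    out <- out[!empty, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Z-score standardization
#'
#' Centers and scales to sample SD 1 (n - 1 denominator). Missing values
#' propagate; a constant (or all-missing) vector is an error.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return Standardized vector of the same length.
#' @export
zscore <- function(values) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L)
    stop("zscore: need at least two distinct finite values (zero SD)")
  (values - mean(v)) / stats::sd(v)
}
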