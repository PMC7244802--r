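#' Default pipeline configuration
#'
#' A complete synthetic-run configuration: the 16-watershed x 3-site
#' design, a set of planted response shapes covering the taxonomy
#' (DBH wedges at winter temperature/PET limits, aligned leaf-mass
#' responses to aridity and wet-quarter PET), a genetic model with a
#' heritable cline on the shaped traits, and mapping of DBH and leaf mass.
#'
#' @param seed integer seed for every stochastic stage.
#' @param output_dir artifact directory.
#' @return Nested list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L, output_dir = "qniche_run") {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    alpha = 0.05,
    method = "rank",
    taus = default_taus(),
    synthetic = list(
      n_watersheds = 16L,
      sites_per_watershed = 3L,
      shapes = list(
        list(trait = "DBH", climate = "max_temp_coldest_month",
             shape = "one_sided_upper", effect = -1),
        list(trait = "DBH", climate = "PET_coldest_quarter",
             shape = "one_sided_upper", effect = -1),
        list(trait = "leaf_mass", climate = "aridity_index_thornthwaite",
             shape = "aligned", effect = 1.2),
        list(trait = "leaf_mass", climate = "PET_wettest_quarter",
             shape = "aligned", effect = 1.2),
        list(trait = "SLA", climate = "continentality",
             shape = "reverse", effect = 1, scale = 2.2)),
      genetics = list(H2 = 0.6, cline = 0.6, plasticity = 0.6,
                      replicates = 3L)),
    mapping = list(
      traits = list(
        list(trait = "DBH",
             climates = c("max_temp_coldest_month", "PET_coldest_quarter")),
        list(trait = "leaf_mass",
             climates = c("aridity_index_thornthwaite",
                          "PET_wettest_quarter"))),
      extent = c(-114.2, -105.5, 33.7, 45.4),
      cellsize = 0.25))
}

validate_config <- function(config) {
  if (is.null(config$seed)) stop("config: seed is required")
  config$alpha <- config$alpha %||% 0.05
  config$method <- config$method %||% "rank"
  config$taus <- config$taus %||% default_taus()
  if (!is.null(config$synthetic)) {
    for (sh in config$synthetic$shapes %||% list()) {
      if (!sh$climate %in% envirem_variables())
        stop("config: unknown climate variable in shapes: ", sh$climate)
      if (!sh$trait %in% field_traits())
        stop("config: unknown trait in shapes: ", sh$trait)
    }
  } else if (!is.null(config$input)) {
    for (p in unlist(config$input))
      if (!file.exists(p)) stop("config: input path does not exist: ", p)
  } else stop("config: need a 'synthetic' block or an 'input' block")
  for (mt in config$mapping$traits %||% list()) {
    bad <- setdiff(mt$climates, envirem_variables())
    if (length(bad))
      stop("config: unknown climate variable in mapping: ",
           paste(bad, collapse = ", "))
  }
  config
}

#' Run the full double-quantile-regression pipeline
#'
#' Orchestrates simulate (or load) -> clone dedup -> site means -> double
#' quantile fits (standardized for classification, raw units for mapping)
#' -> response-shape classification and tallies -> field/garden cline calls
#' and heritability -> constraint maps, writing every stage as a plain file
#' under `config$output_dir` together with a manifest (package version,
#' config hash, seed). Reruns with the same config produce identical fit
#' tables.
#'
#' @param config nested list as from [default_config()], or a path to a
#'   YAML file holding one.
#' @return The output directory, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir <- config$output_dir
  for (d in file.path(dir, c("tables", "fits", "patterns", "calls", "maps")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- config$seed

  # --- simulate or load -----------------------------------------------
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    dat <- stage("simulate", {
      design <- transect_design(
        n_watersheds = syn$n_watersheds %||% 16L,
        sites_per_watershed = syn$sites_per_watershed %||% 3L,
        seed = seed)
      sites <- gen_transects(design)
      gn <- syn$genetics %||% list()
      genetics <- genetic_model(H2 = gn$H2 %||% 0.5,
                                cline = gn$cline %||% 0,
                                plasticity = gn$plasticity %||% 0.8,
                                replicates_per_genotype = gn$replicates %||% 3L)
      shapes <- list()
      for (sh in syn$shapes %||% list()) {
        eff <- sh$effect %||% 1
        sp <- shape_spec(sh$shape, effect = abs(eff),
                         scale = sh$scale %||% 1,
                         family = sh$family %||% "normal")
        if (eff < 0) sp <- flip_shape(sp)   # negative-direction variant
        shapes[[paste(sh$trait, sh$climate, sep = ":")]] <- sp
      }
      ft <- gen_field_traits(sites, shapes, genetics, seed = seed + 1L)
      climate <- gen_climate(sites, climate_model(), seed = seed + 2L)
      # planted (trait-conditional) columns override the elevation model
      for (cl in setdiff(names(ft$site_climate), c("watershed", "band")))
        climate[[cl]] <- ft$site_climate[[cl]]
      garden <- gen_garden(ft$field, genetics, seed = seed + 3L)
      list(field = ft$field, garden = garden, site_climate = climate)
    })
  } else {
    dat <- stage("load", list(
      field = read_field_table(config$input$field),
      garden = if (!is.null(config$input$garden))
        read_garden_table(config$input$garden) else NULL,
      site_climate = utils::read.csv(config$input$site_climate,
                                     stringsAsFactors = FALSE)))
  }

  # --- aggregate -------------------------------------------------------
  field <- stage("dedup", dedup_clones(dat$field))
  sm <- stage("site_means",
              site_means(field, dat$garden, dat$site_climate))
  utils::write.csv(field, file.path(dir, "tables", "field.csv"),
                   row.names = FALSE)
  if (!is.null(dat$garden))
    utils::write.csv(dat$garden, file.path(dir, "tables", "garden.csv"),
                     row.names = FALSE)
  utils::write.csv(sm, file.path(dir, "tables", "site_means.csv"),
                   row.names = FALSE)

  # --- fits ------------------------------------------------------------
  climates <- intersect(config$climates %||% envirem_variables(), names(sm))
  ci <- config$ci %||% TRUE
  field_fits <- stage("fit_field",
                      dqr_table(sm, climates = climates,
                                taus = config$taus, alpha = config$alpha,
                                method = config$method, standardize = TRUE,
                                ci = ci))
  field_fits_raw <- stage("fit_field_raw",
                          dqr_table(sm, climates = climates,
                                    taus = config$taus,
                                    alpha = config$alpha,
                                    method = config$method,
                                    standardize = FALSE, ci = ci))
  utils::write.csv(attr(field_fits, "table"),
                   file.path(dir, "fits", "field_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(field_fits_raw, "table"),
                   file.path(dir, "fits", "field_fits_raw.csv"),
                   row.names = FALSE)
  garden_fits <- NULL
  if (!is.null(dat$garden)) {
    garden_fits <- stage("fit_garden",
                         dqr_table(sm, garden = TRUE, climates = climates,
                                   taus = config$taus,
                                   alpha = config$alpha,
                                   method = config$method,
                                   standardize = TRUE, ci = ci))
    utils::write.csv(attr(garden_fits, "table"),
                     file.path(dir, "fits", "garden_fits.csv"),
                     row.names = FALSE)
  }

  # --- patterns --------------------------------------------------------
  pat <- stage("classify", pattern_table(field_fits))
  utils::write.csv(pat, file.path(dir, "patterns", "patterns_field.csv"),
                   row.names = FALSE)
  for (tr in unique(pat$trait))
    utils::write.csv(summarize_patterns(pat[pat$trait == tr, ]),
                     file.path(dir, "patterns",
                               paste0("tally_", tr, ".csv")),
                     row.names = FALSE)

  # --- cline calls and heritability -----------------------------------
  calls <- NULL
  if (!is.null(garden_fits)) {
    calls <- stage("compare", cline_table(field_fits, garden_fits))
    utils::write.csv(calls, file.path(dir, "calls", "cline_calls.csv"),
                     row.names = FALSE)
    utils::write.csv(consistent_pairs(calls),
                     file.path(dir, "calls", "consistent_pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(heritability_table(dat$garden),
                     file.path(dir, "heritability.csv"), row.names = FALSE)
  }

  # --- mapping ---------------------------------------------------------
  if (!is.null(config$mapping) && !is.null(calls)) {
    stage("map", {
      ext <- config$mapping$extent %||% c(-114.2, -105.5, 33.7, 45.4)
      cs <- config$mapping$cellsize %||% 0.25
      grids <- gen_climate_raster(ext, cs, climate_model(),
                                  seed = seed + 4L)
      cons <- consistent_pairs(calls)
      raw_tab <- attr(field_fits_raw, "table")
      for (mt in config$mapping$traits %||% list()) {
        tr <- mt$trait
        use <- cons[cons$trait == tr &
                      cons$climate %in% (mt$climates %||% cons$climate), ,
                    drop = FALSE]
        if (!nrow(use)) next
        # projection surfaces: rescale the elevation-model raster to the
        # observed site distribution of each mapped variable so projected
        # values sit inside the fitted range
        for (cl in unique(use$climate)) {
          g <- grids[[cl]]
          v <- g$values
          sv <- sm[[cl]]
          g$values <- mean(sv, na.rm = TRUE) +
            (v - mean(v)) / stats::sd(v) * stats::sd(sv, na.rm = TRUE)
          grids[[cl]] <- g
        }
        cg <- map_trait_constraints(raw_tab, use, tr, grids, sm,
                                    field[[tr]])
        if (!is.null(cg))
          write_map(cg, file.path(dir, "maps", tr))
      }
    })
  }

  # --- manifest --------------------------------------------------------
  cfg_yaml <- yaml::as.yaml(config)
  writeLines(cfg_yaml, file.path(dir, "config.yaml"))
  jsonlite::write_json(
    list(package = "qniche",
         version = as.character(utils::packageVersion("qniche")),
         seed = seed, config_hash = fnv1a32(cfg_yaml)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

# Mirror a shape spec across the trait axis (negate both slopes); used for
# planting negative-direction wedges.
flip_shape <- function(s) {
  flipped <- implied_shape(-s$b, -s$d, s$family)
  structure(list(target_shape = flipped, a = s$a, b = -s$b, c = s$c,
                 d = -s$d, family = s$family, support = s$support),
            class = "shape_spec")
}

#' Summarize a completed pipeline run
#'
#' Reads the artifact directory and assembles per-trait pattern tallies,
#' the cline-call matrix, the heritability table, quantile-crossing
#' warnings and map summaries; also writes `report.md` into the directory.
#' Missing artifacts are listed explicitly.
#'
#' @param dir artifact directory from [run_pipeline()].
#' @return Object of class `"qniche_report"` (a list), invisibly printed.
#' @export
report_run <- function(dir) {
  need <- c("manifest.json", "tables/site_means.csv",
            "fits/field_fits.csv", "patterns/patterns_field.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("report_run: incomplete run, missing artifact(s): ",
         paste(missing, collapse = ", "))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  pat <- utils::read.csv(file.path(dir, "patterns", "patterns_field.csv"))
  tallies <- lapply(split(pat, pat$trait), summarize_patterns)
  fits <- utils::read.csv(file.path(dir, "fits", "field_fits.csv"))
  crossings <- unique(fits[fits$crossing, c("trait", "climate")])
  calls_path <- file.path(dir, "calls", "cline_calls.csv")
  calls <- if (file.exists(calls_path)) utils::read.csv(calls_path) else NULL
  h2_path <- file.path(dir, "heritability.csv")
  h2 <- if (file.exists(h2_path)) utils::read.csv(h2_path) else NULL
  maps <- list.files(file.path(dir, "maps"), pattern = "_traitmax\\.asc$")
  rep <- structure(list(manifest = manifest, tallies = tallies,
                        calls = calls, heritability = h2,
                        crossings = crossings,
                        maps = sub("_traitmax\\.asc$", "", maps),
                        dir = dir),
                   class = "qniche_report")
  writeLines(format_report(rep), file.path(dir, "report.md"))
  rep
}

format_report <- function(x) {
  out <- c(sprintf("# qniche run report (seed %s, config %s)",
                   x$manifest$seed, x$manifest$config_hash),
           "", "## Response-pattern tallies")
  for (tr in names(x$tallies)) {
    t <- x$tallies[[tr]]
    out <- c(out, sprintf("- %s: %s", tr,
                          paste(sprintf("%s %d", t$label, t$count),
                                collapse = ", ")))
  }
  if (!is.null(x$calls)) {
    out <- c(out, "", "## Cline calls")
    tab <- table(x$calls$trait, x$calls$call)
    out <- c(out, utils::capture.output(print(tab)))
  } else out <- c(out, "", "## Cline calls", "unavailable (no garden data)")
  if (!is.null(x$heritability)) {
    out <- c(out, "", "## Broad-sense heritability",
             sprintf("- %s: H2 = %.3f (%d genotypes)",
                     x$heritability$trait, x$heritability$H2,
                     x$heritability$n_genotypes))
  }
  if (nrow(x$crossings))
    out <- c(out, "", "## Quantile-crossing warnings",
             sprintf("- %s ~ %s", x$crossings$trait, x$crossings$climate))
  if (length(x$maps))
    out <- c(out, "", "## Maps", sprintf("- %s", x$maps))
  out
}

#' @export
print.qniche_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}
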