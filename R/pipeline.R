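# End-to-end orchestration: build one profile per genome from its
# annotation inputs plus cohort-level COG statistics and species
# delineation. Stages with missing optional inputs are marked skipped with
# a reason rather than failing the run.

PROFILE_SCHEMA_VERSION <- "1.0"

skipped <- function(reason) {
  list(skipped = TRUE, reason = reason)
}

#' Run the full profiling pipeline over a cohort
#'
#' `config` is a list (or path to a YAML file) with:
#' \describe{
#'   \item{genomes}{list of entries: `id`, `size_mb`, `assembly_level`,
#'     and paths `eggnog` (annotations TSV), optionally `ko` (KO TSV) and
#'     `dbcan` (CAZyme TSV).}
#'   \item{ani, dddh}{optional paths to labeled square similarity TSVs.}
#'   \item{landmarks}{optional path to a fully-valued landmark YAML (or a
#'     `trophic_landmarks` object under `landmarks_object`).}
#'   \item{sap}{optional path to a SAP config YAML.}
#'   \item{transporters, polymer_map}{optional config paths (packaged
#'     defaults used when omitted).}
#' }
#'
#' @param config list or YAML path.
#' @param out optional output directory: per-genome profile JSON and
#'   cohort-level TSV matrices are written there.
#' @return list with `profiles` (one per genome), `cog` (counts, z, cv),
#'   `delineation` (or skip marker) and `config_echo` (thresholds used).
#' @export
run_profile <- function(config, out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!length(config$genomes)) {
    stop("config must name at least one genome", call. = FALSE)
  }
  for (g in config$genomes) {
    if (is.null(g$id) || is.null(g$size_mb)) {
      stop("every genome entry needs an id and a size_mb", call. = FALSE)
    }
    if (is.null(g$eggnog)) {
      stop("genome ", g$id, " has no annotation input", call. = FALSE)
    }
  }

  tables <- list()
  records <- list()
  for (g in config$genomes) {
    tab <- read_eggnog_table(g$eggnog, g$id)
    if (!is.null(g$ko)) {
      tab <- merge_annotations(tab, read_ko_table(g$ko, g$id))
    }
    tables[[g$id]] <- tab
    records[[g$id]] <- genome_record(
      g$id, g$size_mb,
      total_orfs = nrow(tab),
      assembly_level = g$assembly_level %||% "contig"
    )
  }
  genomes <- dplyr::bind_rows(records)

  counts <- count_cog_categories(tables)
  cog <- if (length(tables) >= 2) {
    list(
      counts = counts,
      z = zscore_matrix(counts),
      cv = cv_banding(counts),
      long = cog_profile_long(counts)
    )
  } else {
    c(list(counts = counts), skipped("Z-scores and CV require >= 2 genomes"))
  }

  landmarks <- if (!is.null(config$landmarks_object)) {
    config$landmarks_object
  } else if (!is.null(config$landmarks)) {
    read_landmarks(config$landmarks)
  } else {
    read_landmarks()
  }
  landmarks_ready <- all(!is.na(landmarks$oligotroph_value) &
    !is.na(landmarks$copiotroph_value))

  trophic <- if (landmarks_ready) {
    lmc <- landmark_counts(tables, landmarks)
    norm <- normalize_category_counts(lmc, genomes,
      unit = config$normalization_unit %||% "per_mb"
    )
    calls <- score_trophic(norm, landmarks)
    list(calls = calls, summaries = summarize_trophic_all(calls))
  } else {
    skipped("landmark reference values not filled in")
  }

  sap_cfg <- tryCatch(
    if (!is.null(config$sap)) read_sap_config(config$sap) else read_sap_config(),
    error = function(e) NULL
  )
  sap <- if (is.null(sap_cfg)) {
    skipped("no SAP KO configuration")
  } else {
    dplyr::bind_rows(lapply(names(tables), function(id) {
      compute_sap(tables[[id]], records[[id]], sap_cfg)
    }))
  }

  defs <- if (!is.null(config$transporters)) {
    read_transporter_defs(config$transporters)
  } else {
    read_transporter_defs()
  }
  transporters <- lapply(tables, function(tab) {
    comp <- assess_all_systems(tab, defs)
    list(
      completeness = comp,
      capabilities = infer_sugar_capabilities(comp)
    )
  })

  panels <- read_panels()
  panel_results <- lapply(tables, function(tab) {
    lapply(panels, function(p) screen_panel(tab, p))
  })

  cazymes <- list()
  pmap <- if (!is.null(config$polymer_map)) {
    read_polymer_map(config$polymer_map)
  } else {
    read_polymer_map()
  }
  for (g in config$genomes) {
    cazymes[[g$id]] <- if (is.null(g$dbcan)) {
      skipped("no CAZyme annotation input")
    } else {
      polymer_profile(read_dbcan_overview(g$dbcan, g$id), pmap)
    }
  }

  delineation <- if (!is.null(config$ani) && !is.null(config$dddh)) {
    delineate(
      read_similarity_matrices(config$ani, config$dddh),
      ani_threshold = config$ani_threshold %||% 95,
      dddh_threshold = config$dddh_threshold %||% 70
    )
  } else {
    skipped("no similarity matrices supplied")
  }

  profiles <- lapply(names(tables), function(id) {
    list(
      schema_version = PROFILE_SCHEMA_VERSION,
      genome_id = id,
      genome = as.list(genomes[genomes$genome_id == id, ]),
      cog_counts = as.list(unclass(counts)[id, ]),
      trophic = if (is.list(trophic) && isTRUE(trophic$skipped)) {
        trophic
      } else {
        list(
          summary = as.list(trophic$summaries[
            trophic$summaries$genome_id == id,
          ])
        )
      },
      sap = if (is.data.frame(sap)) as.list(sap[sap$genome_id == id, ]) else sap,
      transporters = list(
        capabilities = transporters[[id]]$capabilities,
        n_complete = sum(vapply(
          transporters[[id]]$completeness,
          function(x) x$status == "complete", logical(1)
        ))
      ),
      panels = lapply(panel_results[[id]], function(r) {
        list(verdict = r$verdict, subsystems = r$subsystems)
      }),
      cazymes = if (isTRUE(cazymes[[id]]$skipped)) {
        cazymes[[id]]
      } else {
        cazymes[[id]]$profile
      },
      species_cluster = if (isTRUE(delineation$skipped)) {
        delineation
      } else {
        dl <- delineation$clusters
        as.integer(dl$cluster[dl$genome_id == id])
      }
    )
  })
  names(profiles) <- names(tables)

  result <- list(
    profiles = profiles,
    cog = cog,
    trophic = trophic,
    sap = sap,
    delineation = delineation,
    config_echo = list(
      schema_version = PROFILE_SCHEMA_VERSION,
      normalization_unit = config$normalization_unit %||% "per_mb",
      ani_threshold = config$ani_threshold %||% 95,
      dddh_threshold = config$dddh_threshold %||% 70
    )
  )

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (id in names(profiles)) {
      jsonlite::write_json(
        profiles[[id]],
        file.path(out, paste0(id, ".profile.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
      )
    }
    if (!isTRUE(cog$skipped)) {
      readr::write_tsv(cog$long, file.path(out, "cog_profile.tsv"),
        progress = FALSE)
    }
    if (is.data.frame(sap)) {
      readr::write_tsv(sap, file.path(out, "sap.tsv"), progress = FALSE)
    }
    if (!isTRUE(delineation$skipped)) {
      readr::write_tsv(delineation$clusters,
        file.path(out, "species_clusters.tsv"),
        progress = FALSE
      )
      readr::write_tsv(delineation$pairs,
        file.path(out, "species_pairs.tsv"),
        progress = FALSE
      )
    }
  }
  result
}
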