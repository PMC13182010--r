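# Seeded generators for every input the pipeline consumes: annotation
# tables with controlled per-category count structure (landmark-centered
# Poisson draws), gene-panel presence toggles, machinery detection
# scenarios, CAZyme family counts, and block-structured ANI/dDDH matrices.
# Fixed seeds give byte-identical output; each genome draws from its own
# RNG stream (derived from cohort seed + genome id) so adding a genome to a
# cohort does not perturb the others.

# Filler COG letters used for background genes; disjoint from the general
# letters scored by the packaged landmark set (V, K, T, N, Q, I).
BACKGROUND_LETTERS <- c("C", "E", "F", "G", "H", "J", "M", "O", "P", "R", "S")

#' Specification of one synthetic genome
#'
#' @param genome_id identifier.
#' @param size_mb genome size in megabases.
#' @param archetype `"copiotroph"`, `"oligotroph"`, `"moderate"` (a
#'   configurable fraction of categories on the copiotroph side) or
#'   `"custom"` (explicit per-category normalized means).
#' @param seed integer seed for this genome's RNG streams.
#' @param moderate_fraction fraction of landmark categories drawn on the
#'   copiotroph side under the `"moderate"` archetype (default 0.65,
#'   approximating a 21-of-33 split).
#' @param custom_means named numeric vector of per-Mb category means
#'   (required when `archetype = "custom"`).
#' @param panel_toggles named list/vector: marker name -> probability of
#'   injecting that marker's gene (1 = always).
#' @param sugar_genes,acid_genes numbers of sugar- and acid-metabolism KO
#'   genes to inject (drawn from the SAP config KO sets).
#' @param machinery_scenarios named list: model_id -> character vector of
#'   mandatory roles to leave missing from the scanner detection.
#' @param cazyme_profile named numeric vector: CAZyme family -> mean count.
#' @param n_background_genes number of background genes (Poisson-free
#'   filler carrying ordinary category letters; ~10% left unassigned).
#' @param dispersion optional negative-binomial size parameter; `NULL`
#'   (default) draws plain Poisson counts.
#' @return list of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(genome_id, size_mb = 4.5,
                                  archetype = c("copiotroph", "oligotroph", "moderate", "custom"),
                                  seed = 1L,
                                  moderate_fraction = 0.65,
                                  custom_means = NULL,
                                  panel_toggles = list(),
                                  sugar_genes = 0L, acid_genes = 0L,
                                  machinery_scenarios = list(),
                                  cazyme_profile = numeric(0),
                                  n_background_genes = 2000L,
                                  dispersion = NULL) {
  archetype <- match.arg(archetype)
  if (archetype == "custom" && is.null(custom_means)) {
    stop("archetype 'custom' requires explicit custom_means", call. = FALSE)
  }
  if (size_mb <= 0) stop("size_mb must be positive", call. = FALSE)
  toggles <- unlist(panel_toggles)
  if (length(toggles) && (any(toggles < 0) || any(toggles > 1))) {
    stop("panel toggle fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      genome_id = genome_id, size_mb = size_mb, archetype = archetype,
      seed = as.integer(seed), moderate_fraction = moderate_fraction,
      custom_means = custom_means, panel_toggles = panel_toggles,
      sugar_genes = as.integer(sugar_genes), acid_genes = as.integer(acid_genes),
      machinery_scenarios = machinery_scenarios,
      cazyme_profile = cazyme_profile,
      n_background_genes = as.integer(n_background_genes),
      dispersion = dispersion
    ),
    class = "synthetic_genome_spec"
  )
}

#' A fully-valued synthetic landmark set for testing and simulation
#'
#' Takes the packaged landmark category ids and directions and fills in
#' synthetic per-Mb reference values: for `"+"` categories the average
#' oligotroph at 5 and the average copiotroph at 15 genes per Mb, mirrored
#' for `"-"` categories. These are stand-in values for exercising the
#' scoring machinery, not published references.
#'
#' @param oligo_low,copio_high the two reference levels (genes per Mb).
#' @return a `trophic_landmarks` tibble with all values defined.
#' @export
synthetic_landmarks <- function(oligo_low = 5, copio_high = 15) {
  lm <- read_landmarks()
  plus <- lm$direction == "+"
  lm$oligotroph_value <- ifelse(plus, oligo_low, copio_high)
  lm$copiotroph_value <- ifelse(plus, copio_high, oligo_low)
  validate_landmarks(lm)
}

draw_counts <- function(n, mean, dispersion = NULL) {
  if (is.null(dispersion)) {
    stats::rpois(n, mean)
  } else {
    stats::rnbinom(n, size = dispersion, mu = mean)
  }
}

# Target normalized (per-Mb) value for one landmark category under an
# archetype side. "copio" side: beyond the copiotroph landmark in the
# copiotrophic direction; "oligo" mirrored. Overshoot is 60% of the
# landmark separation, floored away from zero.
archetype_target <- function(side, direction, oligo, copio, overshoot = 0.6) {
  rng <- abs(copio - oligo)
  if (side == "copio") {
    if (direction == "+") copio + overshoot * rng else max(copio - overshoot * rng, 0.25 * copio)
  } else {
    if (direction == "+") max(oligo - overshoot * rng, 0.25 * oligo) else oligo + overshoot * rng
  }
}

#' Generate a synthetic annotation table
#'
#' Per scored landmark category the gene count is drawn Poisson with mean =
#' target normalized value x genome size, the target lying beyond the
#' copiotroph (or oligotroph) landmark according to the archetype. Panel
#' marker genes are injected per the spec's toggles, sugar/acid KO genes
#' per its counts, and background genes fill in ordinary categories.
#' Ranks are sequential, 0-based.
#'
#' @param spec a `synthetic_genome_spec`.
#' @param landmarks a fully-valued `trophic_landmarks` table (e.g.
#'   [synthetic_landmarks()]).
#' @param panels named list of `gene_panel`s used to resolve marker ids for
#'   toggle injection (defaults to the packaged panels).
#' @param sap_cfg SAP config providing the sugar/acid KO pools.
#' @return an `annotation_table`.
#' @export
generate_annotation <- function(spec, landmarks = synthetic_landmarks(),
                                panels = read_panels(),
                                sap_cfg = read_sap_config()) {
  defined <- !is.na(landmarks$oligotroph_value) & !is.na(landmarks$copiotroph_value)
  if (!all(defined)) {
    stop("landmark values must all be defined for simulation", call. = FALSE)
  }
  with_local_seed(derive_seed(spec$seed, paste0(spec$genome_id, ":annotation")), {
    n_cat <- nrow(landmarks)
    side <- switch(spec$archetype,
      copiotroph = rep("copio", n_cat),
      oligotroph = rep("oligo", n_cat),
      moderate = {
        k <- round(spec$moderate_fraction * n_cat)
        c(rep("copio", k), rep("oligo", n_cat - k))
      },
      custom = rep(NA_character_, n_cat)
    )
    target <- vapply(seq_len(n_cat), function(i) {
      if (spec$archetype == "custom") {
        v <- spec$custom_means[[landmarks$category[i]]]
        if (is.null(v) || is.na(v)) {
          stop("custom_means lacks category ", landmarks$category[i],
            call. = FALSE
          )
        }
        v
      } else {
        archetype_target(
          side[i], landmarks$direction[i],
          landmarks$oligotroph_value[i], landmarks$copiotroph_value[i]
        )
      }
    }, numeric(1))
    cat_counts <- draw_counts(n_cat, target * spec$size_mb, spec$dispersion)

    rows <- list()
    is_letter <- nchar(landmarks$category) == 1
    for (i in seq_len(n_cat)) {
      k <- cat_counts[i]
      if (!k) next
      if (is_letter[i]) {
        rows[[length(rows) + 1]] <- tibble(
          cog_categories = replicate(k, landmarks$category[i], simplify = FALSE),
          cog_ids = replicate(k, character(0), simplify = FALSE),
          ko_id = rep(NA_character_, k),
          product = rep(sprintf("category %s protein", landmarks$category[i]), k)
        )
      } else {
        rows[[length(rows) + 1]] <- tibble(
          cog_categories = replicate(k, "S", simplify = FALSE),
          cog_ids = replicate(k, landmarks$category[i], simplify = FALSE),
          ko_id = rep(NA_character_, k),
          product = rep(sprintf("%s family protein", landmarks$category[i]), k)
        )
      }
    }

    # panel marker injection
    for (panel in panels) {
      for (m in panel$markers) {
        p <- spec$panel_toggles[[m$name]]
        if (is.null(p) || is.na(p)) next
        if (stats::runif(1) >= p) next
        id <- m$accepted_ids[1]
        rows[[length(rows) + 1]] <- tibble(
          cog_categories = list(if (m$match_by == "cog_id") character(0) else "R"),
          cog_ids = list(if (m$match_by == "cog_id") id else character(0)),
          ko_id = if (m$match_by == "ko") id else NA_character_,
          product = m$name
        )
        # joint complexes need every member id present
        if (m$match_all && length(m$accepted_ids) > 1) {
          for (id2 in m$accepted_ids[-1]) {
            rows[[length(rows) + 1]] <- tibble(
              cog_categories = list(if (m$match_by == "cog_id") character(0) else "R"),
              cog_ids = list(if (m$match_by == "cog_id") id2 else character(0)),
              ko_id = if (m$match_by == "ko") id2 else NA_character_,
              product = m$name
            )
          }
        }
      }
    }

    # sugar / acid metabolism genes for the SAP index
    inject_kos <- function(pool, n) {
      if (!n) {
        return(NULL)
      }
      tibble(
        cog_categories = replicate(n, "G", simplify = FALSE),
        cog_ids = replicate(n, character(0), simplify = FALSE),
        ko_id = sample(pool, n, replace = TRUE),
        product = rep("carbon metabolism protein", n)
      )
    }
    rows[[length(rows) + 1]] <- inject_kos(sap_cfg$sugar_kos, spec$sugar_genes)
    rows[[length(rows) + 1]] <- inject_kos(sap_cfg$acid_kos, spec$acid_genes)

    # background genes; ~10% without any category assignment
    nb <- spec$n_background_genes
    if (nb > 0) {
      unassigned <- stats::runif(nb) < 0.1
      letters <- sample(BACKGROUND_LETTERS, nb, replace = TRUE)
      rows[[length(rows) + 1]] <- tibble(
        cog_categories = lapply(seq_len(nb), function(j) {
          if (unassigned[j]) character(0) else letters[j]
        }),
        cog_ids = replicate(nb, character(0), simplify = FALSE),
        ko_id = rep(NA_character_, nb),
        product = rep("hypothetical protein", nb)
      )
    }

    df <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
    n <- nrow(df)
    df <- df[sample.int(n), ]
    df$gene_id <- sprintf("%s_%05d", spec$genome_id, seq_len(n))
    df$rank <- seq_len(n) - 1L
    new_annotation_table(spec$genome_id, df)
  })
}

#' Genome record matching a synthetic spec
#'
#' @param spec a `synthetic_genome_spec`.
#' @param annotation the generated `annotation_table` (its gene total
#'   becomes `total_orfs`).
#' @param assembly_level passed through to [genome_record()].
#' @return a `genome_record` row.
#' @export
synthetic_genome_record <- function(spec, annotation,
                                    assembly_level = "chromosome") {
  genome_record(spec$genome_id, spec$size_mb,
    total_orfs = nrow(annotation), assembly_level = assembly_level
  )
}

#' Specification of a synthetic cohort for similarity simulation
#'
#' @param blocks list of character vectors partitioning the genome ids into
#'   planted species blocks.
#' @param within,between lists with `ani_mean`, `ani_sd`, `dddh_mean`,
#'   `dddh_sd` for within-block and between-block pairs.
#' @param seed integer seed.
#' @return list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(blocks,
                                  within = list(ani_mean = 98.5, ani_sd = 0.1, dddh_mean = 89, dddh_sd = 0.6),
                                  between = list(ani_mean = 82, ani_sd = 1.5, dddh_mean = 25, dddh_sd = 2),
                                  seed = 1L) {
  ids <- unlist(blocks)
  if (anyDuplicated(ids)) stop("blocks must be disjoint", call. = FALSE)
  if (within$ani_mean <= between$ani_mean) {
    stop("within-block ANI mean must exceed between-block mean", call. = FALSE)
  }
  structure(
    list(blocks = blocks, genome_ids = ids, within = within,
      between = between, seed = as.integer(seed)),
    class = "synthetic_cohort_spec"
  )
}

#' Generate block-structured ANI/dDDH matrices
#'
#' Pairs within a planted block draw from the within-block distributions,
#' all other pairs from the between-block distributions; draws are clipped
#' to \[0, 100\], matrices are symmetric with diagonal 100.
#'
#' @param cohort a `synthetic_cohort_spec`.
#' @return a `similarity_matrices` object.
#' @export
generate_similarity <- function(cohort) {
  ids <- cohort$genome_ids
  n <- length(ids)
  block_of <- setNames(
    rep(seq_along(cohort$blocks), lengths(cohort$blocks)),
    unlist(cohort$blocks)
  )
  with_local_seed(derive_seed(cohort$seed, "similarity"), {
    ani <- matrix(100, n, n, dimnames = list(ids, ids))
    dddh <- matrix(100, n, n, dimnames = list(ids, ids))
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          par <- if (block_of[ids[i]] == block_of[ids[j]]) cohort$within else cohort$between
          a <- min(max(stats::rnorm(1, par$ani_mean, par$ani_sd), 0), 100)
          d <- min(max(stats::rnorm(1, par$dddh_mean, par$dddh_sd), 0), 100)
          ani[i, j] <- ani[j, i] <- a
          dddh[i, j] <- dddh[j, i] <- d
        }
      }
    }
    similarity_matrices(ani, dddh)
  })
}

#' Generate machinery detection scenarios
#'
#' For each model in the spec's `machinery_scenarios`, emits a scanner
#' detection whose roles are the model's mandatory set minus the scenario's
#' missing roles (cluster ranks placed contiguously), plus a rescue-hit
#' table for the requested subset of missing roles.
#'
#' @param spec a `synthetic_genome_spec`.
#' @param models a `machinery_models` list.
#' @param rescue named list model_id -> roles recoverable by homology
#'   rescue (subset of that scenario's missing roles).
#' @param scanner named list model_id -> scanner source (default
#'   `"txsscan"`).
#' @return list with `detections` (list of `detection_record`) and
#'   `rescue_hits` (named list model_id -> roles).
#' @export
generate_machinery_detections <- function(spec, models, rescue = list(),
                                          scanner = list()) {
  detections <- list()
  offset <- 100L
  for (model_id in names(spec$machinery_scenarios)) {
    model <- models[[model_id]]
    if (is.null(model)) {
      stop("scenario references unknown model: ", model_id, call. = FALSE)
    }
    missing <- as.character(spec$machinery_scenarios[[model_id]])
    bad <- setdiff(missing, model$mandatory_genes)
    if (length(bad)) {
      stop("scenario for ", model_id, " drops unknown role(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    detected <- setdiff(model$mandatory_genes, missing)
    src <- scanner[[model_id]] %||% "txsscan"
    detections[[length(detections) + 1]] <- detection_record(
      spec$genome_id, model_id, detected,
      source = src,
      cluster_gene_ranks = if (length(detected)) {
        seq.int(offset, length.out = length(detected))
      } else {
        NULL
      }
    )
    offset <- offset + 50L
  }
  rescue_hits <- lapply(rescue, as.character)
  list(detections = detections, rescue_hits = rescue_hits)
}

#' Generate synthetic CAZyme counts
#'
#' @param spec a `synthetic_genome_spec` whose `cazyme_profile` maps family
#'   to mean count; counts are Poisson draws.
#' @return a `cazyme_counts` object.
#' @export
generate_cazyme_counts <- function(spec) {
  prof <- spec$cazyme_profile
  if (!length(prof)) {
    return(cazyme_counts(spec$genome_id, setNames(integer(0), character(0))))
  }
  with_local_seed(derive_seed(spec$seed, paste0(spec$genome_id, ":cazyme")), {
    counts <- draw_counts(length(prof), prof, spec$dispersion)
    cazyme_counts(spec$genome_id, setNames(as.integer(counts), names(prof)))
  })
}

#' Write an annotation table in the eggNOG-mapper dialect
#'
#' Emits `#query`, `COG_category`, `eggNOG_OGs`, `KEGG_ko`, `Description`
#' columns readable by [read_eggnog_table()]; used to produce on-disk
#' fixtures from synthetic tables.
#'
#' @param table an `annotation_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eggnog_table <- function(table, path) {
  lines <- c(
    "## synthetic eggNOG-mapper style annotations",
    paste("#query", "COG_category", "eggNOG_OGs", "KEGG_ko", "Description",
      sep = "\t"
    ),
    vapply(seq_len(nrow(table)), function(i) {
      cats <- paste(table$cog_categories[[i]], collapse = "")
      ogs <- paste(sprintf("%s@1|root", table$cog_ids[[i]]), collapse = ",")
      ko <- table$ko_id[i]
      paste(
        table$gene_id[i],
        if (nzchar(cats)) cats else "-",
        if (nzchar(ogs)) ogs else "-",
        if (is.na(ko)) "-" else paste0("ko:", ko),
        if (is.na(table$product[i])) "-" else table$product[i],
        sep = "\t"
      )
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write similarity matrices as labeled square TSVs
#'
#' @param matrices a `similarity_matrices` object.
#' @param ani_path,dddh_path output paths.
#' @return invisibly, the two paths.
#' @export
write_similarity_tsv <- function(matrices, ani_path, dddh_path) {
  dump <- function(m, path) {
    df <- cbind(
      tibble(genome = rownames(m)),
      as.data.frame(m, check.names = FALSE)
    )
    readr::write_tsv(df, path, progress = FALSE)
  }
  dump(matrices$ani, ani_path)
  dump(matrices$dddh, dddh_path)
  invisible(c(ani_path, dddh_path))
}
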