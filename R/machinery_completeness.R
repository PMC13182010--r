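# Completeness adjudication for multi-gene machineries: secretion systems
# (T1SS-T6SS, T4SS subtypes), the flagellum and type IV pili (Tad, MSH,
# T4aP). Detections come from scanner output (MacSyFinder/TXSScan or
# ConjScan dialects) and from KEGG BRITE screens; missing roles can be
# rescued by externally supplied homology hits restricted to the gene
# neighborhood of the detected cluster.
#
# Provenance codes follow the conventional footnote scheme:
#   a  complete by scanner and confirmed by BRITE
#   b  highly incomplete (missing fraction above threshold), not rescued
#   c  incomplete by ConjScan, completed by homology rescue
#   d  incomplete (not rescued, below the highly-incomplete threshold, or
#      any non-rescued incomplete ConjScan detection)
#   e  incomplete by TXSScan, completed by homology rescue
#   f  incomplete by scanner, but a complete version found by BRITE

#' Read machinery model definitions from YAML
#'
#' Each entry: `model_id`, `mandatory_genes` (role names), optional
#' `accessory_genes`, optional `highly_incomplete_fraction` (default 1/3).
#'
#' @param path YAML file; defaults to the packaged secretion/pilus models.
#' @return named list of models, class `machinery_models`.
#' @export
read_machinery_models <- function(path = genotroph_extdata("machinery_models.yaml")) {
  raw <- yaml::read_yaml(path)
  models <- lapply(raw$models, function(e) {
    m <- list(
      model_id = e$model_id,
      mandatory_genes = as.character(e$mandatory_genes),
      accessory_genes = as.character(e$accessory_genes %||% character(0)),
      highly_incomplete_fraction = as.numeric(e$highly_incomplete_fraction %||% (1 / 3))
    )
    validate_machinery_model(m)
    m
  })
  names(models) <- vapply(models, `[[`, character(1), "model_id")
  class(models) <- "machinery_models"
  models
}

validate_machinery_model <- function(model) {
  if (!length(model$mandatory_genes)) {
    stop("model ", model$model_id, " has no mandatory genes", call. = FALSE)
  }
  if (anyDuplicated(model$mandatory_genes)) {
    stop("duplicate mandatory roles in ", model$model_id, call. = FALSE)
  }
  if (model$highly_incomplete_fraction <= 0 || model$highly_incomplete_fraction >= 1) {
    stop("highly_incomplete_fraction must be in (0, 1)", call. = FALSE)
  }
  invisible(model)
}

#' A single machinery detection record
#'
#' @param genome_id,model_id identifiers.
#' @param detected_roles roles reported present.
#' @param source detection source: `"txsscan"`, `"conjscan"` (scanners) or
#'   `"brite"`.
#' @param cluster_gene_ranks optional 0-based gene ranks of the detected
#'   cluster members (scanner sources only).
#' @return list of class `detection_record`.
#' @export
detection_record <- function(genome_id, model_id, detected_roles,
                             source = c("txsscan", "conjscan", "brite"),
                             cluster_gene_ranks = NULL) {
  source <- match.arg(source)
  structure(
    list(
      genome_id = genome_id, model_id = model_id,
      detected_roles = unique(as.character(detected_roles)),
      source = source,
      cluster_gene_ranks = cluster_gene_ranks
    ),
    class = "detection_record"
  )
}

#' Candidate gene ranks in the neighborhood of a cluster
#'
#' Returns the ranks within `window` positions upstream of the cluster's
#' first member and downstream of its last, excluding the cluster members
#' themselves. On a linear replicon the window truncates at the ends; on a
#' circular one it wraps.
#'
#' @param cluster_gene_ranks 0-based ranks of the cluster members (non-empty).
#' @param n_genes total number of genes on the replicon.
#' @param window number of genes inspected on each side (default 10).
#' @param topology `"linear"` or `"circular"`.
#' @return sorted integer vector of candidate ranks.
#' @export
neighborhood_window <- function(cluster_gene_ranks, n_genes, window = 10,
                                topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!length(cluster_gene_ranks)) stop("empty cluster", call. = FALSE)
  if (window < 0) stop("window must be >= 0", call. = FALSE)
  ranks <- sort(as.integer(cluster_gene_ranks))
  if (min(ranks) < 0 || max(ranks) >= n_genes) {
    stop("cluster ranks outside the replicon", call. = FALSE)
  }
  lo <- min(ranks)
  hi <- max(ranks)
  if (window == 0) {
    return(integer(0))
  }
  upstream <- (lo - window):(lo - 1)
  downstream <- (hi + 1):(hi + window)
  cand <- c(upstream, downstream)
  if (topology == "circular") {
    cand <- cand %% n_genes
  } else {
    cand <- cand[cand >= 0 & cand < n_genes]
  }
  sort(setdiff(unique(cand), ranks))
}

#' Adjudicate completeness of one machinery in one genome
#'
#' Roles are unioned across scanner and BRITE detections; `rescue_hits`
#' (roles recovered by homology search of the cluster neighborhood, an
#' external input) may fill remaining gaps. The status and provenance code
#' follow the source pattern: scanner-complete confirmed by BRITE is code
#' `a`; scanner-incomplete with a complete BRITE detection is `f`;
#' scanner-incomplete completed by rescue is `c` (ConjScan) or `e`
#' (TXSScan); an unrescued machinery missing more than the model's
#' highly-incomplete fraction is `b`; any other incomplete state is `d`.
#'
#' @param detections list of `detection_record`s for one genome + model
#'   (may be empty, meaning absent).
#' @param model a machinery model.
#' @param rescue_hits optional character vector of roles recovered by
#'   neighborhood homology search; must be roles of the model.
#' @return list of class `machinery_status`: `genome_id`, `model_id`,
#'   `status`, `provenance_code`, `present_roles`, `missing_roles`,
#'   `missing_fraction`, `scanner`.
#' @export
adjudicate <- function(detections, model, rescue_hits = NULL) {
  validate_machinery_model(model)
  mandatory <- model$mandatory_genes
  known <- c(mandatory, model$accessory_genes)
  if (length(detections)) {
    gids <- unique(vapply(detections, `[[`, character(1), "genome_id"))
    mids <- unique(vapply(detections, `[[`, character(1), "model_id"))
    if (length(gids) != 1 || length(mids) != 1) {
      stop("detections must share one genome and one model", call. = FALSE)
    }
    if (!identical(mids, model$model_id)) {
      stop("detections are for model ", mids, ", not ", model$model_id,
        call. = FALSE
      )
    }
    bad <- setdiff(unique(unlist(lapply(detections, `[[`, "detected_roles"))), known)
    if (length(bad)) {
      stop("detected roles not in model ", model$model_id, ": ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  if (length(rescue_hits)) {
    bad <- setdiff(rescue_hits, known)
    if (length(bad)) {
      stop("rescue roles not in model ", model$model_id, ": ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  sources <- vapply(detections, `[[`, character(1), "source")
  roles_of <- function(src) {
    unique(unlist(lapply(detections[sources %in% src], `[[`, "detected_roles")))
  }
  scan_roles <- intersect(roles_of(c("txsscan", "conjscan")), mandatory)
  brite_roles <- intersect(roles_of("brite"), mandatory)
  scanner <- if ("conjscan" %in% sources) "conjscan" else "txsscan"
  if (!length(detections)) {
    return(structure(
      list(
        genome_id = NA_character_, model_id = model$model_id,
        status = "absent", provenance_code = NA_character_,
        present_roles = character(0), missing_roles = mandatory,
        missing_fraction = 1, scanner = NA_character_
      ),
      class = "machinery_status"
    ))
  }
  scan_complete <- setequal(scan_roles, mandatory) &&
    any(sources %in% c("txsscan", "conjscan"))
  brite_complete <- setequal(brite_roles, mandatory) && any(sources == "brite")
  union_roles <- union(scan_roles, brite_roles)
  missing_before_rescue <- setdiff(mandatory, union_roles)
  rescued <- intersect(rescue_hits %||% character(0), missing_before_rescue)
  present <- union(union_roles, rescued)
  missing <- setdiff(mandatory, present)
  missing_fraction <- length(missing) / length(mandatory)

  if (scan_complete && brite_complete) {
    status <- "complete_scan_confirmed"
    code <- "a"
  } else if (scan_complete) {
    # scanner alone already complete; BRITE silent or partial
    status <- "complete_scan_confirmed"
    code <- "a"
  } else if (!length(missing_before_rescue)) {
    # union of scanner + BRITE complete without rescue
    status <- "complete_brite_only"
    code <- "f"
  } else if (brite_complete) {
    status <- "complete_brite_only"
    code <- "f"
  } else if (!length(missing)) {
    status <- "complete_after_rescue"
    code <- if (scanner == "conjscan") "c" else "e"
  } else if (missing_fraction > model$highly_incomplete_fraction &&
    scanner != "conjscan") {
    status <- "highly_incomplete"
    code <- "b"
  } else {
    status <- "incomplete"
    code <- "d"
  }
  structure(
    list(
      genome_id = unique(vapply(detections, `[[`, character(1), "genome_id")),
      model_id = model$model_id,
      status = status, provenance_code = code,
      present_roles = sort(present), missing_roles = sort(missing),
      missing_fraction = missing_fraction, scanner = scanner
    ),
    class = "machinery_status"
  )
}

#' Summarize machinery statuses across genomes
#'
#' @param statuses list of `machinery_status` objects (several copies of a
#'   model in one genome appear as separate statuses).
#' @return list with `long` (tibble genome_id, model_id, status, code) and
#'   `matrix` (tibble, one row per model, one column per genome holding
#'   `"<n_copies><codes>"`; absent models shown as `"0"`).
#' @export
summarize_machineries <- function(statuses) {
  long <- dplyr::bind_rows(lapply(statuses, function(s) {
    tibble(
      genome_id = s$genome_id, model_id = s$model_id,
      status = s$status, provenance_code = s$provenance_code
    )
  }))
  present <- long[long$status != "absent", ]
  genomes <- unique(long$genome_id[!is.na(long$genome_id)])
  models <- unique(long$model_id)
  cells <- sapply(genomes, function(g) {
    vapply(models, function(m) {
      sub <- present[!is.na(present$genome_id) & present$genome_id == g &
        present$model_id == m, ]
      if (!nrow(sub)) {
        "0"
      } else {
        paste0(nrow(sub), paste(sort(sub$provenance_code), collapse = ""))
      }
    }, character(1))
  })
  cells <- matrix(cells, nrow = length(models), ncol = length(genomes),
    dimnames = list(models, genomes))
  mat <- as_tibble(cbind(tibble(model_id = models), as.data.frame(cells)))
  list(long = long, matrix = mat)
}
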