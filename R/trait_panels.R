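# Ecological gene-panel screens: osmoadaptation (compatible-solute uptake
# and biosynthesis), oxidative stress / high-affinity oxidases, nitrate
# reduction to ammonia, fermentation end products, chemotaxis (MCP/Aer).
#
# A panel is a list of markers. A marker matches by KO id, COG id or a
# gene-symbol regex against the product text; markers sharing a `subsystem`
# label are jointly required for that subsystem to be complete (e.g. the
# proU glycine-betaine transporter needs proV + proW + proX). Multi-id
# complexes (match_all = true) count one copy per complete id set.

#' Read a gene panel definition from YAML
#'
#' Fields: `panel_id`, `verdict_rule`
#' (`any_complete_subsystem` / `all_required` / `report_only`) and
#' `markers`, each with `name`, `match_by` (`ko`, `cog_id`, `gene_symbol`),
#' `accepted_ids`, optional `subsystem`, optional `match_all` (all ids
#' required jointly; copy number is the minimum per-id count) and optional
#' `class` tag (e.g. `high_affinity_oxidase`).
#'
#' @param path YAML file path.
#' @return a list of class `gene_panel`.
#' @export
read_panel <- function(path) {
  raw <- yaml::read_yaml(path)
  markers <- lapply(raw$markers, function(m) {
    list(
      name = m$name,
      match_by = m$match_by %||% "ko",
      accepted_ids = as.character(m$accepted_ids),
      subsystem = m$subsystem %||% NA_character_,
      match_all = isTRUE(m$match_all),
      class = m$class %||% NA_character_
    )
  })
  panel <- list(
    panel_id = raw$panel_id,
    verdict_rule = raw$verdict_rule %||% "report_only",
    markers = markers
  )
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  if (!panel$verdict_rule %in% c("any_complete_subsystem", "all_required", "report_only")) {
    stop("unknown verdict_rule: ", panel$verdict_rule, call. = FALSE)
  }
  nms <- vapply(panel$markers, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("marker names must be unique within panel ", panel$panel_id, call. = FALSE)
  }
  for (m in panel$markers) {
    if (!m$match_by %in% c("ko", "cog_id", "gene_symbol")) {
      stop("unknown match_by '", m$match_by, "' for marker ", m$name, call. = FALSE)
    }
    if (!length(m$accepted_ids)) {
      stop("marker ", m$name, " has no accepted ids", call. = FALSE)
    }
  }
  class(panel) <- "gene_panel"
  panel
}

#' Read all packaged panels
#'
#' @param dir directory of panel YAML files; defaults to the packaged set.
#' @return named list of `gene_panel` objects.
#' @export
read_panels <- function(dir = genotroph_extdata("panels")) {
  files <- list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE)
  panels <- lapply(files, read_panel)
  names(panels) <- vapply(panels, `[[`, character(1), "panel_id")
  panels
}

count_id_matches <- function(annotation, match_by, id) {
  switch(match_by,
    ko = sum(!is.na(annotation$ko_id) & annotation$ko_id == id),
    cog_id = sum(vapply(annotation$cog_ids, function(g) id %in% g, logical(1))),
    gene_symbol = sum(grepl(paste0("\\b", id, "\\b"),
      annotation$product %||% character(0),
      ignore.case = TRUE
    ), na.rm = TRUE),
    stop("unknown match_by: ", match_by, call. = FALSE)
  )
}

marker_copy_number <- function(annotation, marker) {
  per_id <- vapply(marker$accepted_ids, function(id) {
    count_id_matches(annotation, marker$match_by, id)
  }, numeric(1))
  if (marker$match_all) min(per_id) else sum(per_id)
}

#' Screen one genome against a gene panel
#'
#' Copy numbers are counted per marker; a subsystem is complete iff every
#' member marker has copy number >= 1. The panel verdict follows its rule:
#' `any_complete_subsystem` is true iff at least one subsystem (markers
#' without a subsystem label count as singleton subsystems) is complete;
#' `all_required` iff every marker is present; `report_only` yields `NA`.
#'
#' @param annotation an `annotation_table`.
#' @param panel a `gene_panel`.
#' @return list of class `panel_result`: `genome_id`, `panel_id`,
#'   `marker_copies` (tibble `marker`, `subsystem`, `class`, `copies`),
#'   `subsystems` (tibble `subsystem`, `complete`), `verdict`.
#' @export
screen_panel <- function(annotation, panel) {
  validate_panel(panel)
  copies <- dplyr::bind_rows(lapply(panel$markers, function(m) {
    tibble(
      marker = m$name,
      subsystem = ifelse(is.na(m$subsystem), m$name, m$subsystem),
      class = m$class,
      copies = marker_copy_number(annotation, m)
    )
  }))
  subsystems <- copies |>
    dplyr::group_by(subsystem) |>
    dplyr::summarise(complete = all(copies >= 1), .groups = "drop")
  verdict <- switch(panel$verdict_rule,
    any_complete_subsystem = any(subsystems$complete),
    all_required = all(copies$copies >= 1),
    report_only = NA
  )
  structure(
    list(
      genome_id = genome_id(annotation),
      panel_id = panel$panel_id,
      marker_copies = copies,
      subsystems = subsystems,
      verdict = verdict
    ),
    class = "panel_result"
  )
}

#' Oxidative-stress / high-affinity oxidase profile
#'
#' Screens the oxidative panel (markers matched by COG id; multi-COG
#' cytochrome complexes require all their COG ids jointly) and flags the
#' genome as putatively microaerobic iff at least one marker tagged
#' `high_affinity_oxidase` is present as a complete complex.
#'
#' @param annotation an `annotation_table`.
#' @param panel the oxidative `gene_panel` (defaults to the packaged one).
#' @return a `panel_result` with an extra `microaerobe` logical element.
#' @export
oxidative_profile <- function(annotation,
                              panel = read_panel(genotroph_extdata("panels", "oxidative.yaml"))) {
  res <- screen_panel(annotation, panel)
  ha <- res$marker_copies[!is.na(res$marker_copies$class) &
    res$marker_copies$class == "high_affinity_oxidase", ]
  res$microaerobe <- nrow(ha) > 0 && any(ha$copies >= 1)
  res
}

#' Count chemotaxis receptors
#'
#' @param annotation an `annotation_table`.
#' @param mcp_ids KO ids counted as methyl-accepting chemotaxis proteins.
#' @param aer_ids KO ids for the aerotaxis/energy sensor Aer.
#' @return list with `n_mcp` (integer) and `aer_present` (logical).
#' @export
count_mcps <- function(annotation, mcp_ids = "K03406", aer_ids = "K03776") {
  if (!length(mcp_ids) || !length(aer_ids)) {
    stop("mcp_ids and aer_ids must be non-empty", call. = FALSE)
  }
  ko <- annotation$ko_id
  list(
    n_mcp = sum(!is.na(ko) & ko %in% mcp_ids),
    aer_present = any(!is.na(ko) & ko %in% aer_ids)
  )
}

#' Panel results as a presence/copy-number matrix
#'
#' @param results list of `panel_result`s for one panel across genomes.
#' @return tibble, one row per marker, one column per genome (copy numbers).
#' @export
panel_matrix <- function(results) {
  long <- dplyr::bind_rows(lapply(results, function(r) {
    tibble(
      genome_id = r$genome_id,
      marker = r$marker_copies$marker,
      copies = r$marker_copies$copies
    )
  }))
  tidyr::pivot_wider(long, names_from = "genome_id", values_from = "copies")
}
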