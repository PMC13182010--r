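# Parsers for the annotation-tool output dialects the pipeline consumes:
# eggNOG-mapper ".annotations" tables (COG categories / COG ids / KOs),
# two-column BlastKOALA KO tables, and labeled square ANI/dDDH matrices.
# Everything downstream works from the annotation_table produced here.

#' Create a genome metadata record
#'
#' @param genome_id unique genome identifier.
#' @param size_mb genome size in megabases (> 0).
#' @param total_orfs total number of annotated ORFs (CDS); used as the
#'   denominator for per-ORF normalizations. May be `NA` if unknown.
#' @param assembly_level one of `"contig"`, `"scaffold"`, `"chromosome"`.
#' @param label free-text strain label.
#' @return a one-row tibble of class `genome_record`.
#' @export
genome_record <- function(genome_id, size_mb, total_orfs = NA_integer_,
                          assembly_level = c("contig", "scaffold", "chromosome"),
                          label = genome_id) {
  assembly_level <- match.arg(assembly_level)
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (!is.numeric(size_mb) || length(size_mb) != 1L || is.na(size_mb) || size_mb <= 0) {
    stop("size_mb must be a positive number", call. = FALSE)
  }
  if (!is.na(total_orfs) && total_orfs < 0) {
    stop("total_orfs must be nonnegative", call. = FALSE)
  }
  out <- tibble(
    genome_id = genome_id, size_mb = as.numeric(size_mb),
    total_orfs = as.integer(total_orfs), assembly_level = assembly_level,
    label = label
  )
  class(out) <- c("genome_record", class(out))
  out
}

new_annotation_table <- function(genome_id, df) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  required <- c("gene_id", "cog_categories", "cog_ids", "ko_id", "product", "rank")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("annotation table missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(df$gene_id)) {
    dups <- unique(df$gene_id[duplicated(df$gene_id)])
    stop(
      "duplicate gene_id in genome '", genome_id, "': ",
      paste(head(dups, 5), collapse = ", "),
      call. = FALSE
    )
  }
  ranks <- df$rank[!is.na(df$rank)]
  if (anyDuplicated(ranks)) {
    stop("gene ranks must be unique within a genome", call. = FALSE)
  }
  out <- as_tibble(df[required])
  attr(out, "genome_id") <- genome_id
  class(out) <- c("annotation_table", class(out))
  out
}

#' Genome id of an annotation table
#' @param x an `annotation_table`.
#' @return the genome identifier string.
#' @export
genome_id <- function(x) {
  attr(x, "genome_id")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(
    "<annotation_table> genome", genome_id(x), "-", nrow(x), "genes\n"
  )
  NextMethod()
}

# Split a COG-category string ("GT", "-", "") into recognized single letters.
# Letters outside the prokaryotic alphabet (including the eukaryote-specific
# B/Y/Z) are dropped; the caller aggregates and warns once per file.
split_cog_letters <- function(s) {
  if (is.na(s) || s %in% c("", "-")) {
    return(character(0))
  }
  letters <- strsplit(toupper(gsub("[^A-Za-z]", "", s)), "")[[1]]
  unique(letters)
}

#' Read an eggNOG-mapper annotations table
#'
#' Parses the eggNOG-mapper `.annotations` TSV dialect: lines starting with
#' `##` are comments, the header row may carry a leading `#`. Mandatory
#' columns are `query` (gene id) and `COG_category`; `eggNOG_OGs` (for COG
#' ids), `KEGG_ko` and `Description` are used when present. Multi-letter
#' COG-category strings are split into single letters; `-` or empty means no
#' assignment. COG-category letters outside the recognized prokaryotic
#' alphabet are dropped with a warning. Gene rank is the 0-based data-row
#' order.
#'
#' @param path path to the annotations file.
#' @param genome_id genome identifier to stamp on the table.
#' @return an `annotation_table`.
#' @export
read_eggnog_table <- function(path, genome_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^##", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no header found in ", path, call. = FALSE)
  lines[1] <- sub("^#", "", lines[1])
  df <- readr::read_tsv(I(paste(lines, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  mandatory <- c("query", "COG_category")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop(
      "eggNOG table ", path, " lacks mandatory column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  n <- nrow(df)
  cats_raw <- if (n) lapply(df$COG_category, split_cog_letters) else list()
  dropped <- unique(unlist(lapply(cats_raw, setdiff, y = COG_ALPHABET)))
  if (length(dropped)) {
    warning(
      "dropping unrecognized/eukaryotic COG category letter(s) in ",
      basename(path), ": ", paste(sort(dropped), collapse = ", "),
      call. = FALSE
    )
    cats_raw <- lapply(cats_raw, intersect, y = COG_ALPHABET)
  }
  ogs <- if ("eggNOG_OGs" %in% names(df)) df$eggNOG_OGs else rep(NA_character_, n)
  cog_ids <- lapply(seq_len(n), function(i) {
    if (is.na(ogs[i])) {
      return(character(0))
    }
    unique(regmatches(ogs[i], gregexpr("COG[0-9]{4}", ogs[i]))[[1]])
  })
  ko_raw <- if ("KEGG_ko" %in% names(df)) df$KEGG_ko else rep(NA_character_, n)
  ko_id <- vapply(ko_raw, function(s) {
    if (is.na(s) || s %in% c("", "-")) {
      return(NA_character_)
    }
    m <- regmatches(s, regexpr("K[0-9]{5}", s))
    if (length(m)) m else NA_character_
  }, character(1), USE.NAMES = FALSE)
  product <- if ("Description" %in% names(df)) df$Description else rep(NA_character_, n)
  new_annotation_table(genome_id, tibble(
    gene_id = df$query,
    cog_categories = if (n) cats_raw else list(),
    cog_ids = cog_ids,
    ko_id = ko_id,
    product = product,
    rank = if (n) seq_len(n) - 1L else integer(0)
  ))
}

#' Read a two-column gene-to-KO table (BlastKOALA dialect)
#'
#' Each line is `gene_id<TAB>KO`; a blank KO field means no assignment and
#' the gene is retained with `ko_id` absent. KO tokens must match
#' `K` + 5 digits.
#'
#' @inheritParams read_eggnog_table
#' @return an `annotation_table` with only `ko_id` populated (no COG data,
#'   no ranks).
#' @export
read_ko_table <- function(path, genome_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  gene <- vapply(parts, function(p) p[1], character(1))
  ko <- vapply(parts, function(p) if (length(p) >= 2) trimws(p[2]) else "", character(1))
  bad <- which(nzchar(ko) & !grepl("^K[0-9]{5}$", ko))
  if (length(bad)) {
    stop(
      "malformed KO token(s) in ", basename(path), " at line(s) ",
      paste(head(bad, 10), collapse = ", "), ": ",
      paste(head(ko[bad], 10), collapse = ", "),
      call. = FALSE
    )
  }
  n <- length(gene)
  new_annotation_table(genome_id, tibble(
    gene_id = gene,
    cog_categories = replicate(n, character(0), simplify = FALSE),
    cog_ids = replicate(n, character(0), simplify = FALSE),
    ko_id = ifelse(nzchar(ko), ko, NA_character_),
    product = rep(NA_character_, n),
    rank = rep(NA_integer_, n)
  ))
}

#' Merge two annotation tables for the same genome
#'
#' Gene-wise union: COG categories and COG ids are unioned, the KO id is the
#' unique non-missing value (a conflict errors), the rank is the smallest
#' defined rank. Merging is commutative, so KO assignments can be layered
#' onto a COG table in either order with an identical result.
#'
#' @param x,y `annotation_table`s with the same genome id.
#' @return the merged `annotation_table`, rows ordered by rank then gene id.
#' @export
merge_annotations <- function(x, y) {
  if (!identical(genome_id(x), genome_id(y))) {
    stop("cannot merge annotation tables from different genomes (",
      genome_id(x), " vs ", genome_id(y), ")",
      call. = FALSE
    )
  }
  all_genes <- sort(unique(c(x$gene_id, y$gene_id)))
  ix <- match(all_genes, x$gene_id)
  iy <- match(all_genes, y$gene_id)
  pick <- function(i, col, tab, empty) {
    if (is.na(i)) empty else tab[[col]][[i]]
  }
  rows <- lapply(seq_along(all_genes), function(k) {
    cats <- sort(unique(c(
      pick(ix[k], "cog_categories", x, character(0)),
      pick(iy[k], "cog_categories", y, character(0))
    )))
    ids <- sort(unique(c(
      pick(ix[k], "cog_ids", x, character(0)),
      pick(iy[k], "cog_ids", y, character(0))
    )))
    kos <- unique(stats::na.omit(c(
      pick(ix[k], "ko_id", x, NA_character_),
      pick(iy[k], "ko_id", y, NA_character_)
    )))
    if (length(kos) > 1) {
      stop("conflicting KO ids for gene ", all_genes[k], ": ",
        paste(kos, collapse = " vs "),
        call. = FALSE
      )
    }
    prods <- unique(stats::na.omit(c(
      pick(ix[k], "product", x, NA_character_),
      pick(iy[k], "product", y, NA_character_)
    )))
    ranks <- stats::na.omit(c(
      pick(ix[k], "rank", x, NA_integer_),
      pick(iy[k], "rank", y, NA_integer_)
    ))
    tibble(
      gene_id = all_genes[k],
      cog_categories = list(cats),
      cog_ids = list(ids),
      ko_id = if (length(kos)) kos else NA_character_,
      product = if (length(prods)) sort(prods)[1] else NA_character_,
      rank = if (length(ranks)) as.integer(min(ranks)) else NA_integer_
    )
  })
  df <- dplyr::bind_rows(rows)
  ord <- order(is.na(df$rank), df$rank, df$gene_id)
  new_annotation_table(genome_id(x), df[ord, ])
}

#' Write / read the canonical internal annotation TSV
#'
#' Column order: `gene_id`, `cog_categories` (comma-joined letters),
#' `cog_ids` (comma-joined), `ko_id`, `product`, `rank`. A round trip through
#' this format reproduces the table exactly.
#'
#' @param table an `annotation_table`.
#' @param path output path.
#' @return `write_annotation_tsv` returns `path` invisibly;
#'   `read_annotation_tsv` returns the `annotation_table`.
#' @export
write_annotation_tsv <- function(table, path) {
  df <- tibble(
    gene_id = table$gene_id,
    cog_categories = vapply(table$cog_categories, paste, character(1), collapse = ","),
    cog_ids = vapply(table$cog_ids, paste, character(1), collapse = ","),
    ko_id = table$ko_id,
    product = table$product,
    rank = table$rank
  )
  header <- paste0("# genotroph annotation table\t", genome_id(table))
  writeLines(header, path)
  suppressWarnings(readr::write_tsv(df, path, append = TRUE, col_names = TRUE,
    na = ""))
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "#")) {
    stop("not a canonical annotation TSV: ", path, call. = FALSE)
  }
  gid <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][2]
  df <- readr::read_tsv(I(paste(lines[-1], collapse = "\n")),
    col_types = readr::cols(
      gene_id = readr::col_character(),
      cog_categories = readr::col_character(),
      cog_ids = readr::col_character(),
      ko_id = readr::col_character(),
      product = readr::col_character(),
      rank = readr::col_integer()
    ),
    na = character(0), progress = FALSE
  )
  split_csv <- function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1]]
  }
  n <- nrow(df)
  new_annotation_table(gid, tibble(
    gene_id = df$gene_id,
    cog_categories = if (n) lapply(df$cog_categories, split_csv) else list(),
    cog_ids = if (n) lapply(df$cog_ids, split_csv) else list(),
    ko_id = ifelse(nzchar(df$ko_id), df$ko_id, NA_character_),
    product = ifelse(nzchar(df$product), df$product, NA_character_),
    rank = df$rank
  ))
}

#' Construct a validated ANI/dDDH matrix pair
#'
#' Both matrices are aligned to the same genome order, symmetrized by the
#' arithmetic mean of reciprocal entries, and the diagonal is forced to 100.
#'
#' @param ani,dddh square numeric matrices with identical dimnames (order
#'   may differ), entries in percent.
#' @return an object of class `similarity_matrices`: a list with
#'   `genome_ids`, `ani`, `dddh`.
#' @export
similarity_matrices <- function(ani, dddh) {
  validate_sim <- function(m, what) {
    if (!is.matrix(m) || nrow(m) != ncol(m)) {
      stop(what, " matrix must be square", call. = FALSE)
    }
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      stop(what, " matrix must be labeled", call. = FALSE)
    }
    if (!identical(sort(rownames(m)), sort(colnames(m)))) {
      stop(what, " matrix row/column labels differ", call. = FALSE)
    }
    if (any(is.na(m)) || any(m < 0) || any(m > 100)) {
      stop(what, " entries must lie in [0, 100]", call. = FALSE)
    }
    m[rownames(m), rownames(m), drop = FALSE]
  }
  ani <- validate_sim(ani, "ANI")
  dddh <- validate_sim(dddh, "dDDH")
  if (!identical(sort(rownames(ani)), sort(rownames(dddh)))) {
    stop("ANI and dDDH genome labels differ", call. = FALSE)
  }
  ids <- rownames(ani)
  dddh <- dddh[ids, ids, drop = FALSE]
  sym <- function(m) {
    m <- (m + t(m)) / 2
    diag(m) <- 100
    m
  }
  structure(
    list(genome_ids = ids, ani = sym(ani), dddh = sym(dddh)),
    class = "similarity_matrices"
  )
}

#' Read labeled square ANI and dDDH matrices from TSV
#'
#' Each file is a labeled square matrix (first column = genome labels,
#' header = genome labels). The two files must carry the same label set;
#' the dDDH matrix is re-ordered to the ANI order. Asymmetric pairs are
#' symmetrized by their mean and the diagonal is forced to 100.
#'
#' @param ani_path,dddh_path file paths.
#' @return a `similarity_matrices` object.
#' @export
read_similarity_matrices <- function(ani_path, dddh_path) {
  read_labeled <- function(path) {
    df <- readr::read_tsv(path,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    labels <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- labels
    m
  }
  similarity_matrices(read_labeled(ani_path), read_labeled(dddh_path))
}

#' @export
print.similarity_matrices <- function(x, ...) {
  cat(
    "<similarity_matrices>", length(x$genome_ids), "genomes: ",
    paste(head(x$genome_ids, 5), collapse = ", "),
    if (length(x$genome_ids) > 5) "..." else "", "\n"
  )
  invisible(x)
}
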