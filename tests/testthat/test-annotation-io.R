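test_that("eggNOG parsing splits categories, extracts COG ids and KOs", {
  tab <- read_eggnog_table(genotroph_extdata("example_eggnog.tsv"), "gA")
  expect_s3_class(tab, "annotation_table")
  expect_identical(genome_id(tab), "gA")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$cog_categories, list("G", c("G", "T"), character(0)))
  expect_equal(tab$cog_ids[[1]], c("COG1263", "COG1264"))
  expect_equal(tab$ko_id, c("K02777", "K03407", NA))
  expect_equal(tab$rank, 0:2)
})

test_that("eggNOG parsing handles empty data and missing optional fields", {
  empty <- tmp_lines(c("## comment", "#query\tCOG_category"))
  tab <- read_eggnog_table(empty, "gE")
  expect_equal(nrow(tab), 0)

  # a file without KO/OG/Description columns still parses; optionals absent
  minimal <- tmp_lines(c("#query\tCOG_category", "g1\tG"))
  tab2 <- read_eggnog_table(minimal, "gM")
  expect_true(is.na(tab2$ko_id))
  expect_equal(tab2$cog_ids[[1]], character(0))
})

test_that("eggNOG parsing rejects bad input and drops eukaryotic letters", {
  no_col <- tmp_lines(c("#query\tother", "g1\tx"))
  expect_error(read_eggnog_table(no_col, "g"), "COG_category")

  dup <- tmp_lines(c("#query\tCOG_category", "g1\tG", "g1\tT"))
  expect_error(read_eggnog_table(dup, "g"), "duplicate gene_id")

  euk <- tmp_lines(c("#query\tCOG_category", "g1\tGB", "g2\tZ"))
  expect_warning(tab <- read_eggnog_table(euk, "g"), "B, Z")
  expect_equal(tab$cog_categories, list("G", character(0)))
})

test_that("KO table parsing keeps blank-KO rows and validates tokens", {
  tab <- read_ko_table(genotroph_extdata("example_ko.tsv"), "gA")
  expect_equal(nrow(tab), 5)
  expect_equal(sum(!is.na(tab$ko_id)), 3)
  expect_equal(tab$ko_id[1], "K02777")

  single <- tmp_lines("g1\tK03406")
  expect_equal(read_ko_table(single, "g")$ko_id, "K03406")

  blank <- tmp_lines("g1\t")
  tb <- read_ko_table(blank, "g")
  expect_equal(nrow(tb), 1)
  expect_true(is.na(tb$ko_id))

  bad <- tmp_lines(c("g1\tK1234", "g2\tfoo"))
  expect_error(read_ko_table(bad, "g"), "malformed KO")
})

test_that("annotation merge is commutative and layers KO onto COG data", {
  cog <- read_eggnog_table(genotroph_extdata("example_eggnog.tsv"), "gA")
  ko <- read_ko_table(genotroph_extdata("example_ko.tsv"), "gA")
  ab <- merge_annotations(cog, ko)
  ba <- merge_annotations(ko, cog)
  expect_identical(ab, ba)
  # genes only in the KO file are appended; COG genes keep their data
  expect_equal(nrow(ab), 5)
  expect_equal(ab$ko_id[ab$gene_id == "gene4"], "K00844")
  expect_equal(ab$cog_categories[ab$gene_id == "gene2"][[1]], c("G", "T"))
  expect_error(
    merge_annotations(cog, read_ko_table(tmp_lines("g\tK00001"), "other")),
    "different genomes"
  )
})

test_that("canonical TSV round-trips an annotation table exactly", {
  tab <- read_eggnog_table(genotroph_extdata("example_eggnog.tsv"), "gA")
  path <- tempfile(fileext = ".tsv")
  write_annotation_tsv(tab, path)
  back <- read_annotation_tsv(path)
  expect_identical(back$gene_id, tab$gene_id)
  expect_identical(back$cog_categories, tab$cog_categories)
  expect_identical(back$cog_ids, tab$cog_ids)
  expect_identical(back$ko_id, tab$ko_id)
  expect_identical(back$rank, tab$rank)
  expect_identical(genome_id(back), "gA")
})

test_that("similarity matrices validate, align and symmetrize", {
  # singleton
  one <- matrix(100, 1, 1, dimnames = list("a", "a"))
  sm1 <- similarity_matrices(one, one)
  expect_equal(sm1$genome_ids, "a")

  # asymmetric pair is mean-symmetrized
  m <- matrix(c(100, 98.4, 98.6, 100), 2, 2, byrow = TRUE,
    dimnames = list(c("a", "b"), c("a", "b")))
  sm <- similarity_matrices(m, m)
  expect_equal(sm$ani["a", "b"], 98.5)
  expect_equal(sm$ani["b", "a"], 98.5)
  expect_equal(unname(diag(sm$dddh)), c(100, 100))

  # permuted labels in the dDDH file are aligned to the ANI order
  ids <- c("a", "b", "c")
  ani <- sim_matrix(ids, c(98, 80, 81))
  dddh_perm <- sim_matrix(c("c", "a", "b"), c(20, 21, 85))
  ani_path <- tempfile(); dddh_path <- tempfile()
  write_similarity_tsv(
    structure(list(genome_ids = ids, ani = ani, dddh = ani), class = "similarity_matrices"),
    ani_path, tempfile()
  )
  df <- cbind(data.frame(genome = rownames(dddh_perm)), as.data.frame(dddh_perm))
  readr::write_tsv(df, dddh_path, progress = FALSE)
  sm3 <- read_similarity_matrices(ani_path, dddh_path)
  expect_equal(sm3$genome_ids, ids)
  expect_equal(sm3$dddh["a", "b"], 85) # c-a=20, c-b=21, a-b=85 in permuted file
  expect_equal(sm3$dddh["a", "c"], 20)

  # validation errors
  bad <- matrix(c(100, 101, 99, 100), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(similarity_matrices(bad, bad), "0, 100")
  expect_error(
    similarity_matrices(one, matrix(100, 1, 1, dimnames = list("b", "b"))),
    "labels differ"
  )
})
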