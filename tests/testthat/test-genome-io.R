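test_that("FASTA reading normalizes case, truncates headers, rejects bad input", {
  path <- write_lines_tmp(c(">chrI some description", "acgt"), ".fa")
  genome <- read_genome_fasta(path)
  expect_identical(names(genome), "chrI")
  expect_identical(as.character(genome[["chrI"]]), "ACGT")

  path2 <- write_lines_tmp(c(">c1", "ACGTN", ">c2", "TTTT"), ".fa")
  genome2 <- read_genome_fasta(path2)
  expect_length(genome2, 2)
  expect_identical(as.character(genome2[["c2"]]), "TTTT")

  bad <- write_lines_tmp(c(">c1", "ACXT"), ".fa")
  expect_error(read_genome_fasta(bad), "outside|invalid|malformed")
  expect_error(read_genome_fasta(tempfile()), "not found")
})

test_that("GFF3 gene parsing extracts records and rejects invalid rows", {
  gff <- write_lines_tmp(c(
    "##gff-version 3",
    "chrI\t.\tgene\t901\t1900\t.\t+\t.\tID=g1",
    "chrI\t.\tmRNA\t901\t1900\t.\t+\t.\tID=t1;Parent=g1",
    "chrI\t.\tgene\t2500\t2900\t.\t-\t.\tID=g2;Name=foo"
  ), ".gff3")
  genes <- read_gff_genes(gff)
  expect_equal(nrow(genes), 2)
  expect_equal(genes$gene_id, c("g1", "g2"))
  expect_equal(genes[genes$gene_id == "g1", ]$length, 1000)
  expect_equal(genes[genes$gene_id == "g2", ]$strand, "-")

  inverted <- write_lines_tmp(
    "chrI\t.\tgene\t1900\t901\t.\t+\t.\tID=g1", ".gff3")
  expect_error(read_gff_genes(inverted), "inverted")

  no_id <- write_lines_tmp(
    "chrI\t.\tgene\t901\t1900\t.\t+\t.\tName=foo", ".gff3")
  expect_error(read_gff_genes(no_id), "missing ID")
})

test_that("gene length filter is strict and order-preserving", {
  genes <- data.frame(gene_id = c("a", "b", "c"), contig = "chrI",
                      strand = "+", start = 1L,
                      end = c(500L, 501L, 499L),
                      length = c(500L, 501L, 499L))
  kept <- filter_by_length(genes, 500)
  expect_identical(kept$gene_id, "b")
  expect_equal(nrow(filter_by_length(genes[0, ], 500)), 0)

  many <- data.frame(gene_id = sprintf("g%d", 1:1000), contig = "chrI",
                     strand = "+", start = 1L, end = 600L, length = 600L)
  expect_equal(nrow(filter_by_length(many)), 1000)
  expect_identical(filter_by_length(many)$gene_id, many$gene_id)
})

toy_genome <- function(n = 3000, seed = 11) {
  Biostrings::DNAStringSet(c(chrI = random_seq(n, seed)))
}

test_that("promoter windows follow the stated coordinate conventions", {
  genome <- toy_genome()
  genes <- data.frame(gene_id = c("plus", "minus"), contig = "chrI",
                      strand = c("+", "-"), start = c(1001L, 1200L),
                      end = c(1900L, 2400L), length = c(900L, 1201L))
  p <- extract_promoters(genome, genes, 100, 100)
  expect_equal(p$window_start, c(900L, 2300L))
  expect_equal(p$window_end, c(1100L, 2500L))
  expect_equal(nchar(p$sequence), c(200L, 200L))

  # hand-indexed check on the plus-strand window
  contig <- as.character(genome[["chrI"]])
  expect_identical(p$sequence[1], substr(contig, 901, 1100))
  # minus-strand promoter is the reverse complement of its plus window
  expect_identical(
    p$sequence[2],
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(contig, 2301, 2500)))))
})

test_that("edge policy drops or clips and conserves gene counts", {
  genome <- toy_genome(1000)
  genes <- data.frame(gene_id = c("edge", "ok"), contig = "chrI",
                      strand = "+", start = c(50L, 500L),
                      end = c(700L, 990L), length = c(651L, 491L))
  dropped <- extract_promoters(genome, genes, 100, 100, "drop")
  expect_equal(dropped$gene_id, "ok")
  report <- attr(dropped, "dropped")
  expect_equal(report$gene_id, "edge")
  expect_equal(nrow(dropped) + nrow(report), nrow(genes))

  clipped <- extract_promoters(genome, genes, 100, 100, "clip")
  expect_equal(nrow(clipped), 2)
  expect_true(clipped$clipped[clipped$gene_id == "edge"])
  expect_equal(nchar(clipped$sequence[clipped$gene_id == "edge"]), 149)

  bad <- genes
  bad$contig <- c("chrI", "chrZ")
  expect_error(extract_promoters(genome, bad), "ok")
})

test_that("promoters round-trip through FASTA", {
  genome <- toy_genome()
  genes <- data.frame(gene_id = c("g1", "g2"), contig = "chrI",
                      strand = c("+", "-"), start = c(600L, 1500L),
                      end = c(1400L, 2600L), length = c(801L, 1101L))
  p <- extract_promoters(genome, genes)
  path <- tempfile(fileext = ".fa")
  write_promoters_fasta(p, path)
  back <- read_genome_fasta(path)
  expect_identical(as.character(back), setNames(p$sequence, p$gene_id))
})

test_that("extraction is invariant under genome mirroring", {
  genome <- toy_genome(4000, seed = 23)
  n <- Biostrings::width(genome)[[1]]
  genes <- data.frame(gene_id = sprintf("g%d", 1:4), contig = "chrI",
                      strand = c("+", "-", "+", "-"),
                      start = c(600L, 1200L, 2100L, 3000L),
                      end = c(1100L, 1900L, 2800L, 3800L))
  genes$length <- genes$end - genes$start + 1L

  mirrored_genome <- Biostrings::reverseComplement(genome)
  names(mirrored_genome) <- "chrI"
  mirrored <- data.frame(
    gene_id = genes$gene_id, contig = "chrI",
    strand = ifelse(genes$strand == "+", "-", "+"),
    start = n - genes$end + 1L, end = n - genes$start + 1L,
    length = genes$length)

  p1 <- extract_promoters(genome, genes)
  p2 <- extract_promoters(mirrored_genome, mirrored)
  expect_identical(setNames(p1$sequence, p1$gene_id),
                   setNames(p2$sequence, p2$gene_id))
})
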