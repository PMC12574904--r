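test_that("delimited expression files read back exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,g2,g3", "1,0,2", "0,0,5"), path)
  x <- read_expression(path)
  expect_s3_class(x, "expression_matrix")
  expect_equal(n_cells(x), 2)
  expect_equal(n_genes(x), 3)
  expect_equal(gene_names(x), c("g1", "g2", "g3"))
  expect_false(is_log_transformed(x))
  expect_equal(unname(unclass(x))[, ], matrix(c(1, 0, 0, 0, 2, 5), 2),
               ignore_attr = TRUE)

  # tab-delimited auto-detection
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tg2", "3\t4"), path2)
  expect_equal(gene_names(read_expression(path2)), c("g1", "g2"))
})

test_that("degenerate and malformed delimited inputs error", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("g1,g2,g3", empty)
  expect_error(read_expression(empty), "no data rows")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,g1", "1,2"), dup)
  expect_error(read_expression(dup), "duplicate gene names")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("g1,g2", "1,2", "3,oops"), bad)
  suppressWarnings(expect_error(read_expression(bad), "line 3"))

  expect_error(read_expression("no/such/file.csv"), "not found")
})

test_that("MTX triplets and delimited text yield identical matrices", {
  x <- tiny_counts()
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "x.csv")
  mtx <- file.path(dir, "x.mtx")
  write_expression(x, csv)
  write_expression(x, mtx)
  from_csv <- read_expression(csv)
  from_mtx <- read_expression(mtx)
  expect_equal(unclass(from_mtx), unclass(from_csv), ignore_attr = TRUE)
  expect_equal(gene_names(from_mtx), gene_names(x))
  expect_equal(cell_ids(from_mtx), cell_ids(x))
  # full round trip is exact for the mtx path (cell ids preserved)
  expect_equal(unname(unclass(from_mtx)), unname(unclass(x)))
})

test_that("log transform is ln(x+1), refuses double application", {
  x <- expression_matrix(matrix(c(1, 3, 0, 0), 2),
                         gene_names = c("a", "b"))
  y <- log_transform(x)
  expect_true(is_log_transformed(y))
  expect_equal(unname(unclass(y)), matrix(c(log(2), log(4), 0, 0), 2),
               ignore_attr = TRUE)
  expect_error(log_transform(y), "already")

  # closed forms: 0 -> 0, e-1 -> 1
  z <- log_transform(expression_matrix(matrix(c(0, exp(1) - 1), 1),
                                       gene_names = c("a", "b")))
  expect_equal(unname(unclass(z)), matrix(c(0, 1), 1), ignore_attr = TRUE)
})

test_that("log transform is strictly monotone entrywise and keeps zeros", {
  set.seed(42)
  v <- matrix(rexp(60), 10, 6)
  v[sample(60, 10)] <- 0
  x <- expression_matrix(v, gene_names = paste0("g", 1:6))
  y <- unclass(log_transform(x))
  expect_true(all((y == 0) == (v == 0)))
  o1 <- order(as.vector(v))
  expect_equal(order(as.vector(y)), o1)
})

test_that("cell QC retains exactly the in-bounds cells", {
  # cell 1: 399 detected genes -> removed at default min_genes = 400
  m <- 500
  v <- rbind(
    c(rep(1, 399), rep(0, m - 399)),           # 399 detected
    c(rep(1, 500), rep(0, m - 500)),           # 500 detected, 500 UMIs
    rep(25, m)                                  # 500 detected, 12500 UMIs
  )
  x <- expression_matrix(v, gene_names = paste0("g", seq_len(m)))
  kept <- filter_cells(x)
  expect_equal(cell_ids(kept), cell_ids(x)[2])

  # mitochondrial fraction: one of three cells above 3%
  genes <- c("mt-Nd1", paste0("g", 1:9))
  v2 <- matrix(1, 3, 10)
  v2[1, ] <- c(4, rep(96 / 9, 9))   # 4% mito
  v2[2, ] <- c(2, rep(98 / 9, 9))   # 2% mito
  v2[3, ] <- c(0, rep(1, 9))        # 0% mito
  x2 <- expression_matrix(v2, gene_names = genes)
  kept2 <- filter_cells(x2, min_genes = 1, max_genes = 100, max_umi = 1e6)
  # independent recount over cells
  expected <- vapply(1:3, function(i) {
    sum(v2[i, startsWith(tolower(genes), "mt-")]) / sum(v2[i, ]) <= 0.03
  }, logical(1))
  expect_equal(cell_ids(kept2), cell_ids(x2)[expected])
  expect_equal(sum(expected), 2)
})

test_that("cell QC is idempotent and errors with per-criterion counts", {
  set.seed(1)
  v <- matrix(rpois(100 * 30, 3), 100, 30)
  x <- expression_matrix(v, gene_names = paste0("g", 1:30))
  once <- filter_cells(x, min_genes = 10, max_genes = 30, max_umi = 120)
  twice <- filter_cells(once, min_genes = 10, max_genes = 30, max_umi = 120)
  expect_equal(unclass(once), unclass(twice))

  err <- expect_error(filter_cells(x, min_genes = 31),
                      "gene-count bound removed 100")
  expect_error(filter_cells(log_transform(x)), "raw counts")
})

test_that("gene filter drops all-zero columns and name matches", {
  v <- cbind(c(1, 2), c(0, 0), c(3, 1), c(2, 2), c(5, 0))
  x <- expression_matrix(v, gene_names = c("Actb", "Dead1", "mt-Co1",
                                           "Rps1", "Gm1234"))
  kept <- filter_genes(x, drop_all_zero = TRUE,
                       drop_name_patterns = list("^mt-", "^Rps"))
  # independent recount: Dead1 all-zero, mt-Co1 and Rps1 by pattern
  expect_equal(gene_names(kept), c("Actb", "Gm1234"))

  # function predicates work, survivors keep column order
  kept2 <- filter_genes(x, drop_all_zero = FALSE,
                        drop_name_patterns = list(function(n) n == "Actb"))
  expect_equal(gene_names(kept2), c("Dead1", "mt-Co1", "Rps1", "Gm1234"))

  expect_error(filter_genes(x, drop_name_patterns = list(".*")), "all genes")
})

test_that("ground-truth reader dedups, restricts to the universe, warns", {
  dir <- withr::local_tempdir()
  ef <- file.path(dir, "edges.csv")
  tf <- file.path(dir, "tfs.txt")
  writeLines(c("a,b", "a,b", "a,c", "B,a"), ef)
  writeLines(c("a"), tf)
  expect_warning(
    truth <- read_ground_truth(ef, tf, gene_universe = c("a", "b")),
    "absent from the TF list")
  # duplicates collapsed, (a,c) outside universe dropped, case folded
  expect_equal(nrow(truth$edges), 2)
  expect_equal(truth$n_dropped, 1)
  expect_setequal(paste(truth$edges$regulator, truth$edges$target),
                  c("a b", "b a"))

  writeLines(c("x,y"), ef)
  expect_error(read_ground_truth(ef, tf, gene_universe = c("a", "b")),
               "no ground-truth edges")
})

test_that("larger edge lists keep exactly the in-universe edges", {
  set.seed(3)
  regs <- paste0("tf", 1:5)
  tgts <- paste0("g", 1:8)
  edges <- unique(data.frame(
    regulator = sample(regs, 30, replace = TRUE),
    target = sample(tgts, 30, replace = TRUE)))
  universe <- c(regs[1:4], tgts[1:6])
  inside <- edges$regulator %in% universe & edges$target %in% universe
  truth <- ground_truth(edges, regs, universe)
  expect_equal(nrow(truth$edges), sum(inside))
  expect_equal(truth$n_dropped, sum(!inside))
})
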