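test_that("residue encoding maps letters to index values", {
  expect_identical(encode_residues("III", get_index("HP")), rep(4.5, 3))
  expect_identical(encode_residues("A", "Mw"), 89.09)
  ones <- stats::setNames(rep(1, 20), aa_alphabet())
  tab <- structure(list(name = "U", values = ones, units = "", source = ""),
                   class = "aa_index_table")
  expect_identical(encode_residues("WYACD", tab), rep(1, 5))
})

test_that("electrotopological state matches hand-derived and oracle values", {
  # hand evaluation: ES1 = 1 - 1/4 - 2/9, ES2 = 2, ES3 = 3 + 2/9 + 1/4
  expect_equal(apply_es(c(1, 2, 3)),
               c(0.527778, 2.0, 3.472222), tolerance = 1e-6)
  expect_identical(apply_es(rep(2.5, 7)), rep(2.5, 7))  # constant array fixed
  expect_identical(apply_es(3.14), 3.14)                # empty neighbour sum

  set.seed(101)
  for (i in 1:25) {
    v <- stats::rnorm(sample(2:200, 1))
    expect_equal(apply_es(v), es_naive(v), tolerance = 1e-12)
  }
})

test_that("the ES operator conserves the array total", {
  set.seed(202)
  for (i in 1:50) {
    v <- stats::rnorm(sample(1:500, 1), sd = 10)
    expect_equal(sum(apply_es(v)), sum(v), tolerance = 1e-9)
  }
})

test_that("group extraction picks the right positions", {
  arr <- c(10, 20, 30, 40)
  expect_identical(extract_group(arr, "ACFA", "ALA"), c(10, 40))
  expect_identical(extract_group(arr, "ACFA", "PRT"), arr)
  expect_identical(extract_group(c(1, 2, 3), "ACD", "TRP"), numeric(0))
})

test_that("the group catalogue has 30 groups with valid memberships", {
  groups <- residue_groups()
  expect_length(groups, 30L)
  expect_setequal(groups$PRT, aa_alphabet())
  for (g in groups) expect_true(all(g %in% aa_alphabet()))
  expect_setequal(groups$CHG, union(groups$PCG, groups$NCG))
  singles <- groups[1:20]
  expect_setequal(unlist(singles), aa_alphabet())
})

test_that("aggregation operators match closed forms", {
  expect_equal(aggregate_op(c(3, 4), "N2"), 5)
  expect_equal(aggregate_op(c(2, 8), "GM"), 4)
  expect_equal(aggregate_op(rep(1, 4), "SE"), 2)  # uniform over 4 entries
  expect_equal(aggregate_op(1:10, "AR"), 5.5)
  expect_equal(aggregate_op(c(1, 2, 4), "HM"), 3 / (1 + 1 / 2 + 1 / 4))
  expect_equal(aggregate_op(c(-1, 2, -3), "N1"), 6)
  expect_equal(aggregate_op(c(-1, 2, -3), "N3"), 36^(1 / 3))
  expect_equal(aggregate_op(c(1, 3), "VA"), 1)    # population variance
  # quartiles use the inclusive linear-interpolation convention
  expect_equal(aggregate_op(1:5, "Q1"), unname(stats::quantile(1:5, 0.25)))
  expect_equal(aggregate_op(1:8, "Q3"), unname(stats::quantile(1:8, 0.75)))
})

test_that("degenerate aggregation inputs resolve by the totality policy", {
  for (op in aggregation_operators()) {
    expect_identical(aggregate_op(numeric(0), op), 0, info = op)
  }
  expect_identical(aggregate_op(c(0, 1, 2), "GM"), 0)
  expect_identical(aggregate_op(c(0, 1, 2), "HM"), 0)
  expect_identical(aggregate_op(c(0, 0), "SE"), 0)
  expect_identical(aggregate_op(rep(5, 4), "SK"), 0)
  expect_identical(aggregate_op(rep(5, 4), "KU"), 0)
})

test_that("operator order statistics are mutually consistent", {
  set.seed(33)
  for (i in 1:200) {
    x <- stats::rnorm(sample(1:40, 1), sd = sample(1:5, 1))
    a <- aggregate_all(x)
    expect_true(a[["MN"]] <= a[["Q1"]] + 1e-12)
    expect_true(a[["Q1"]] <= a[["MD"]] + 1e-12)
    expect_true(a[["MD"]] <= a[["Q3"]] + 1e-12)
    expect_true(a[["Q3"]] <= a[["MX"]] + 1e-12)
    expect_true(a[["VA"]] >= 0)
    expect_true(a[["SE"]] >= -1e-12 && a[["SE"]] <= log2(length(x)) + 1e-12)
    # cross-check the one-shot path against R's reference implementations
    expect_equal(a[["MD"]], stats::median(x))
    expect_equal(a[["VA"]], mean((x - mean(x))^2))
    expect_equal(a[["N2"]], sqrt(sum(x^2)))
  }
})

test_that("feature naming and matrix shape follow the four-axis convention", {
  ds <- tiny_dataset()
  cfg <- featurize_config(indices = c("HP", "Mw"), vicinity = c("NO", "ES"),
                          groups = c("ARM", "PRT"), operators = c("AR", "N2"))
  dm <- featurize(ds, cfg, drop_constant = FALSE)
  expect_identical(ncol(dm$values), 2L * 2L * 2L * 2L)
  expect_true("HP_NO_ARM_AR" %in% colnames(dm$values))
  expect_true("Mw_ES_PRT_N2" %in% colnames(dm$values))
  expect_identical(rownames(dm$values), ds$ids)
  # HP_NO_ARM_AR is the mean hydropathy over aromatic residues
  s1 <- ds$sequences[[1]]
  arm <- extract_group(encode_residues(s1, "HP"), s1, "ARM")
  expect_equal(dm$values[1, "HP_NO_ARM_AR"], mean(arm))
})

test_that("an all-aromatic sequence makes ARM and PRT columns coincide", {
  ds <- labeled_dataset(c(x = "FFFF", y = "FWFY"))
  dm <- featurize(ds, featurize_config(indices = "HP", groups = c("ARM", "PRT")),
                  drop_constant = FALSE)
  expect_equal(dm$values[, "HP_NO_ARM_AR"], dm$values[, "HP_NO_PRT_AR"])
  expect_equal(dm$values[, "HP_ES_ARM_N2"], dm$values[, "HP_ES_PRT_N2"])
})

test_that("composition (NO) columns are permutation invariant, ES columns are not", {
  set.seed(55)
  cfg <- featurize_config(indices = "HP", groups = c("PRT", "AHR"))
  for (i in 1:10) {
    s <- random_seq(40)
    sh <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    ds <- labeled_dataset(c(a = s, b = sh))
    dm <- featurize(ds, cfg, drop_constant = FALSE)$values
    no_cols <- grepl("_NO_", colnames(dm))
    expect_equal(dm[1, no_cols], dm[2, no_cols], tolerance = 1e-12)
  }
  # explicit 1D counter-witness: one transposition changes an ES column
  ds <- labeled_dataset(c(a = "IRRRRR", b = "RIRRRR"))
  dm <- featurize(ds, featurize_config(indices = "HP", vicinity = "ES",
                                       groups = "ILE", operators = "MX"),
                  drop_constant = FALSE)$values
  expect_gt(abs(dm[1, 1] - dm[2, 1]), 0.1)
})

test_that("constant columns are dropped at generation and logged", {
  ds <- tiny_dataset()
  dm <- featurize(ds, featurize_config(indices = "HP"))
  expect_true(length(dm$dropped) > 0)        # e.g. SE over singleton groups
  expect_false(any(dm$dropped %in% colnames(dm$values)))
  rng <- apply(dm$values, 2, function(col) diff(range(col)))
  expect_true(all(rng > 0))
})

test_that("descriptor matrices round-trip through TSV", {
  ds <- tiny_dataset()
  dm <- featurize(ds, featurize_config(indices = "HP", groups = c("PRT", "GLY")))
  path <- tempfile(fileext = ".tsv")
  write_descriptor_matrix(dm, path)
  back <- read_descriptor_matrix(path)
  expect_equal(back$values, dm$values, tolerance = 1e-12)
  expect_identical(back$labels, dm$labels)
})

test_that("the autocorrelation vicinity stub refuses to run", {
  expect_error(apply_ac(1:5), "not implemented")
})
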