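test_that("GPR parsing honors structure, case and parentheses", {
  leaf <- parse_gpr("QPRT")
  expect_s3_class(leaf, "gpr_expr")
  expect_identical(leaf$op, "gene")
  expect_identical(leaf$gene, "QPRT")

  tree <- parse_gpr("G1 and (G2 or G3)")
  expect_identical(tree$op, "and")
  expect_identical(tree$children[[1]]$gene, "G1")
  expect_identical(tree$children[[2]]$op, "or")
  expect_identical(format(tree), "G1 and (G2 or G3)")

  # n-ary flattening and operator precedence (and binds tighter)
  expect_length(parse_gpr("A or B or C")$children, 3)
  prec <- parse_gpr("A or B and C")
  expect_identical(prec$op, "or")
  expect_identical(prec$children[[2]]$op, "and")
  # case-insensitive keywords
  expect_identical(format(parse_gpr("a AND b Or c")), "(a and b) or c")
})

test_that("GPR round-trips through its canonical string", {
  set.seed(14)
  for (i in 1:50) {
    s <- random_gpr_string()
    canon <- format(parse_gpr(s))
    expect_identical(format(parse_gpr(canon)), canon)
  }
})

test_that("malformed GPR rules raise parse errors with a position", {
  expect_error(parse_gpr("and G1"), "position 1.*dangling")
  expect_error(parse_gpr("G1 and"), "unexpected end")
  expect_error(parse_gpr("(G1 or G2"), "unbalanced")
  expect_error(parse_gpr("G1) or G2"), "unexpected")
  expect_error(parse_gpr("   "), "nonempty")
})

test_that("RAS evaluation implements min/sum with absent-gene rules", {
  expr <- c(A = 3, B = 5, QPRT = 7.5)
  expect_equal(reaction_activity_score(parse_gpr("QPRT"), expr), 7.5)
  expect_equal(reaction_activity_score(parse_gpr("A and B"), expr), 3)
  expect_equal(reaction_activity_score(parse_gpr("A or B"), expr), 8)
  # unmeasured gene: contributes 0 to OR, skipped in AND
  expect_equal(reaction_activity_score(parse_gpr("A or ZZZ"), expr), 3)
  expect_equal(reaction_activity_score(parse_gpr("A and ZZZ"), expr), 3)
  # all leaves unmeasured -> NaN, not 0
  expect_true(is.nan(reaction_activity_score(parse_gpr("X or Y"), expr)))
  # OR -> max alternative
  expect_equal(reaction_activity_score(parse_gpr("A or B"), expr,
                                       or_mode = "max"), 5)
})

test_that("recursive evaluation equals the table-driven oracle", {
  set.seed(15)
  genes <- LETTERS[1:8]
  for (i in 1:200) {
    gpr <- parse_gpr(random_gpr_string(6, genes))
    # random TPM vector over a random subset (some genes unmeasured)
    measured <- sample(genes, sample.int(8, 1))
    expr <- setNames(runif(length(measured), 0, 50), measured)
    for (mode in c("sum", "max")) {
      got <- reaction_activity_score(gpr, expr, or_mode = mode)
      ref <- oracle_gpr_eval(gpr, expr, or_mode = mode)
      if (is.nan(ref)) expect_true(is.nan(got)) else expect_equal(got, ref)
    }
  }
})

test_that("RAS is monotone and 1-homogeneous", {
  set.seed(16)
  genes <- LETTERS[1:6]
  for (i in 1:100) {
    gpr <- parse_gpr(random_gpr_string(6, genes))
    expr <- setNames(runif(6, 0, 10), genes)
    base <- reaction_activity_score(gpr, expr)
    # bumping any single gene never decreases the score
    g <- sample(genes, 1)
    bumped <- expr
    bumped[g] <- bumped[g] + runif(1, 0, 5)
    expect_gte(reaction_activity_score(gpr, bumped), base)
    # homogeneity: RAS(c * expr) = c * RAS(expr)
    c0 <- runif(1, 0, 3)
    expect_equal(reaction_activity_score(gpr, c0 * expr), c0 * base)
  }
})

test_that("compute_ras_matrix maps reactions over samples", {
  expr <- matrix(c(1, 2, 3, 10, 20, 30), nrow = 3,
                 dimnames = list(paste0("S", 1:3), c("G1", "G2")))
  model <- pathway_model(
    "toy",
    list(list(id = "RX", name = "x", substrates = "a", products = "b",
              gpr = "G1"),
         list(id = "RY", name = "y", substrates = "b", products = "c",
              gpr = NULL)),
    data.frame(id = c("a", "b", "c"), name = c("a", "b", "c")))
  ras <- compute_ras_matrix(model, expr)
  # single-leaf reaction column equals that gene's TPM column
  expect_equal(ras[, "RX"], expr[, "G1"])
  expect_true(all(is.nan(ras[, "RY"])))      # spontaneous -> NaN
  # doubling TPM doubles every RAS; permuting samples permutes rows
  expect_equal(compute_ras_matrix(model, 2 * expr)[, "RX"],
               2 * ras[, "RX"])
  perm <- expr[c(3, 1, 2), ]
  expect_equal(compute_ras_matrix(model, perm)[, "RX"], ras[, "RX"][c(3, 1, 2)])
  expect_error(compute_ras_matrix(model, -expr), "nonnegative")
})

test_that("packaged Trp subnetwork is the expected KP reconstruction", {
  model <- load_trp_subnetwork()
  expect_silent(validate_pathway_model(model))
  ids <- vapply(model$reactions, `[[`, "", "id")
  expect_true("R24a" %in% ids)
  r24a <- model$reactions[[which(ids == "R24a")]]
  expect_identical(r24a$gpr_string, "QPRT")
  expect_identical(r24a$substrates, "QA")
  expect_identical(r24a$products, "NAMN")
  # KP arm metabolites all present as nodes
  kp_arm <- c("Trp", "Kyn", "KA", "Anth", "3OHKyn", "Xanth", "3OHAnth",
              "PA", "QA")
  expect_true(all(kp_arm %in% model$metabolites$id))
  # serotonin branch and salvage entry
  expect_true(all(c("5OHTrp", "Sero", "NAM", "NAD") %in%
                    model$metabolites$id))
})

test_that("pathway model survives a JSON round-trip", {
  model <- load_trp_subnetwork()
  f <- withr::local_tempfile(fileext = ".json")
  write_pathway_model(model, f)
  back <- read_pathway_model(f)
  expect_identical(vapply(back$reactions, `[[`, "", "id"),
                   vapply(model$reactions, `[[`, "", "id"))
  expect_identical(vapply(back$reactions, `[[`, "", "gpr_string"),
                   vapply(model$reactions, `[[`, "", "gpr_string"))
  cfg <- synthetic_config(n_patients = 4, seed = 17)
  co <- generate_cohort(cfg)
  expr <- generate_expression(co, cfg)
  expect_equal(compute_ras_matrix(back, expr),
               compute_ras_matrix(model, expr))
})

test_that("model validation catches broken inputs", {
  mets <- data.frame(id = c("a", "b"), name = c("a", "b"))
  expect_error(pathway_model("x", list(
    list(id = "R1", name = "", substrates = "a", products = "zz",
         gpr = NULL)), mets), "undeclared")
  expect_error(pathway_model("x", list(
    list(id = "R1", name = "", substrates = "a", products = "b", gpr = NULL),
    list(id = "R1", name = "", substrates = "b", products = "a", gpr = NULL)),
    mets), "duplicate")
  expect_error(pathway_model("x", list(
    list(id = "R1", name = "", substrates = character(), products = "b",
         gpr = NULL)), mets), "substrates")
})
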