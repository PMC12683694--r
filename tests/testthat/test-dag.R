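growth_dag <- function() {
  causal_dag(c("drought -> rice", "drought -> growth", "rice -> growth"),
             exposure = "rice", outcome = "growth")
}

survival_dag <- function() {
  causal_dag(c("drought -> rice", "drought -> survival",
               "rice -> survival", "predators -> survival"),
             exposure = "rice", outcome = "survival",
             unobserved = "predators")
}

test_that("confounded exposure has one backdoor path, closed by adjustment", {
  dag <- growth_dag()
  open <- open_backdoor_paths(dag)
  expect_length(open, 1)
  expect_equal(as.character(open[[1]]), c("rice", "drought", "growth"))
  expect_length(open_backdoor_paths(dag, "drought"), 0)
  ## a pure chain has no backdoor paths at all
  chain <- causal_dag(c("X -> M", "M -> Y"), exposure = "X", outcome = "Y")
  expect_length(open_backdoor_paths(chain), 0)
})

test_that("minimal adjustment sets match the study's causal structure", {
  sets_g <- minimal_adjustment_sets(growth_dag())
  expect_length(sets_g, 1)
  expect_equal(sets_g[[1]], "drought")
  ## unobserved predators are ignorable for the survival outcome
  sets_s <- minimal_adjustment_sets(survival_dag())
  expect_length(sets_s, 1)
  expect_equal(sets_s[[1]], "drought")
  ## unconfounded single edge: empty set is the unique minimal set
  xy <- causal_dag(c("X -> Y"), exposure = "X", outcome = "Y")
  sets <- minimal_adjustment_sets(xy)
  expect_length(sets, 1)
  expect_identical(sets[[1]], character(0))
})

test_that("shipped DAG fixtures reproduce the adjustment analysis", {
  path_g <- system.file("extdata", "dag_growth.dag", package = "growsurv")
  dag <- read_dag(path_g, exposure = "rice", outcome = "growth")
  expect_equal(minimal_adjustment_sets(dag)[[1]], "drought")
  path_s <- system.file("extdata", "dag_survival.dag", package = "growsurv")
  dag_s <- read_dag(path_s, exposure = "rice", outcome = "survival")
  expect_equal(dag_s$unobserved, "predators")
  expect_equal(minimal_adjustment_sets(dag_s)[[1]], "drought")
})

test_that("cycles are rejected and structure is validated", {
  expect_error(causal_dag(c("A -> B", "B -> C", "C -> A"),
                          exposure = "A", outcome = "B"), "cycle")
  expect_error(causal_dag(c("A -> B"), exposure = "A", outcome = "A"),
               "differ")
})

test_that("d-separation agrees with a moralization oracle on small DAGs", {
  ## exhaustive over all DAGs on 3 labelled nodes
  nodes3 <- LETTERS[1:3]
  prs <- t(combn(nodes3, 2))
  for (code in 0:(3^3 - 1)) {
    states <- (code %/% 3^(0:2)) %% 3  # 0 none, 1 forward, 2 backward
    edges <- NULL
    for (e in 1:3) {
      if (states[e] == 1) edges <- rbind(edges, prs[e, ])
      if (states[e] == 2) edges <- rbind(edges, prs[e, 2:1])
    }
    if (is.null(edges)) next
    dag <- tryCatch(causal_dag(edges, exposure = edges[1, 1],
                               outcome = edges[1, 2], nodes = nodes3),
                    error = function(e) NULL)
    if (is.null(dag)) next   # orientation produced a directed cycle
    for (pair_i in 1:3) {
      a <- prs[pair_i, 1]; b <- prs[pair_i, 2]
      others <- setdiff(nodes3, c(a, b))
      for (Z in list(character(0), others)) {
        expect_identical(d_separated(dag, a, b, Z),
                         moral_dsep(dag$edges, a, b, Z, nodes3),
                         info = sprintf("code %d pair %s-%s |%s", code, a,
                                        b, paste(Z, collapse = ",")))
      }
    }
  }
})

test_that("d-separation matches the oracle on random 4-6 node DAGs", {
  set.seed(17)
  for (rep in 1:120) {
    n <- sample(4:6, 1)
    edges <- random_dag_edges(n)
    if (nrow(edges) < 2) next
    nodes <- LETTERS[seq_len(n)]
    dag <- causal_dag(edges, exposure = edges[1, 1], outcome = edges[1, 2],
                      nodes = nodes)
    ## all pairs, conditioning sets of size <= 2
    prs <- t(combn(nodes, 2))
    for (pair_i in seq_len(nrow(prs))) {
      a <- prs[pair_i, 1]; b <- prs[pair_i, 2]
      others <- setdiff(nodes, c(a, b))
      Zs <- c(list(character(0)), as.list(others))
      if (length(others) >= 2) {
        two <- combn(others, 2)
        Zs <- c(Zs, lapply(seq_len(ncol(two)), function(j) two[, j]))
      }
      for (Z in Zs)
        expect_identical(d_separated(dag, a, b, Z),
                         moral_dsep(dag$edges, a, b, Z, nodes))
    }
  }
})

test_that("adjustment sets agree with a brute-force subset search", {
  set.seed(23)
  checked <- 0
  for (rep in 1:60) {
    n <- sample(4:6, 1)
    edges <- random_dag_edges(n, 0.45)
    if (nrow(edges) < 2) next
    nodes <- LETTERS[seq_len(n)]
    x <- edges[1, 1]; y <- edges[1, 2]
    dag <- causal_dag(edges, exposure = x, outcome = y, nodes = nodes)
    got <- minimal_adjustment_sets(dag)
    ## oracle: valid iff x _|_ y given S in the graph with x's outgoing
    ## edges removed (backdoor graph), over subsets of non-descendants
    desc <- growsurv:::dag_descendants(dag, x)
    cand <- setdiff(nodes, c(desc, y))
    eb <- edges[edges[, 1] != x, , drop = FALSE]
    subsets <- list(character(0))
    for (k in seq_along(cand))
      subsets <- c(subsets, lapply(seq_len(ncol(combn(cand, k))),
                                   function(j) combn(cand, k)[, j]))
    valid <- Filter(function(S) {
      if (nrow(eb) == 0) return(TRUE)
      moral_dsep(eb, x, y, S, nodes)
    }, subsets)
    minimal <- Filter(function(S) {
      !any(vapply(valid, function(v)
        length(v) < length(S) && all(v %in% S), logical(1)))
    }, valid)
    norm <- function(l) sort(vapply(l, function(s)
      paste(sort(s), collapse = "+"), character(1)))
    expect_identical(norm(got), norm(minimal))
    checked <- checked + 1
  }
  expect_gt(checked, 30)
})

test_that("implied independencies are found and testable on data", {
  chain <- causal_dag(c("X -> Y", "Y -> Z"), exposure = "X", outcome = "Z")
  imp <- implied_independencies(chain)
  expect_length(imp, 1)
  expect_equal(imp[[1]]$a, "X"); expect_equal(imp[[1]]$b, "Z")
  expect_equal(imp[[1]]$given, "Y")
  ## growth DAG: rice and growth are both connected to drought; the only
  ## non-adjacent pair is none (complete graph) -> no statements
  expect_length(implied_independencies(growth_dag()), 0)
  ## data simulated from the chain SCM: the implication should hold
  set.seed(5)
  n <- 2000
  X <- rnorm(n); Y <- 0.8 * X + rnorm(n); Z <- 0.7 * Y + rnorm(n)
  res <- test_independencies(imp, data.frame(X = X, Y = Y, Z = Z))
  expect_true(res$consistent[1])
  expect_lt(abs(res$partial_cor[1]), 0.08)
  ## and a violated independence is detected
  res2 <- test_independencies(list(list(a = "X", b = "Z",
                                        given = character(0))),
                              data.frame(X = X, Y = Y, Z = Z))
  expect_false(res2$consistent[1])
  expect_error(test_independencies(imp, data.frame(X = X, Y = Y)),
               "missing column")
})

test_that("independence tests are calibrated on DAG-consistent data", {
  ## diamond DAG: A -> B, A -> C, B -> D, C -> D
  dag <- causal_dag(c("A -> B", "A -> C", "B -> D", "C -> D"),
                    exposure = "B", outcome = "D")
  imp <- implied_independencies(dag)
  expect_true(length(imp) >= 1)
  set.seed(11)
  pass <- replicate(40, {
    n <- 800
    A <- rnorm(n); B <- 0.6 * A + rnorm(n); C <- 0.5 * A + rnorm(n)
    D <- 0.5 * B + 0.4 * C + rnorm(n)
    res <- test_independencies(imp, data.frame(A = A, B = B, C = C, D = D))
    all(res$consistent)
  })
  expect_gte(mean(pass), 0.85)  # ~alpha-level failures allowed
})
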