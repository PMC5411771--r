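test_that("successor queries on a constructed two-k-mer graph", {
  f <- exactish_filter("ACGT", 3) # k-mers ACG, CGT
  g <- dbg(f, 3)
  expect_identical(unname(dbg_successors(g, "ACG")), "T")
  expect_identical(names(dbg_successors(g, "ACG")), "CGT")
  expect_identical(unname(dbg_predecessors(g, "CGT")), "A")
  # dead end (note: a k-mer whose successor is its own reverse
  # complement, like ACG -> CGT, is *not* a dead end in the canonical
  # graph; ACT has no such hairpin)
  f2 <- exactish_filter("ACT", 3)
  expect_length(dbg_successors(dbg(f2, 3), "ACT"), 0)
})

test_that("interior genome k-mers have exactly one successor and
           predecessors mirror successors on the opposite strand", {
  k <- 21
  genome <- genome_unique_km1(5000, k, seed = 3)
  g <- dbg(exactish_filter(genome, k), k)
  set.seed(8)
  pos <- sample(2:(nchar(genome) - k), 50)
  for (p in pos) {
    x <- substr(genome, p, p + k - 1)
    succ <- dbg_successors(g, x)
    expect_length(succ, 1)
    expect_identical(unname(succ), substr(genome, p + k, p + k))
    # strand symmetry: successors of x <-> predecessors of revcomp(x)
    expect_identical(unname(dbg_predecessors(g, revcomp(x))),
                     revcomp(unname(succ)))
  }
})

test_that("look-ahead prunes short spurs and halts at true forks", {
  k <- 9
  # trunk long enough to survive any look-ahead walk
  trunk <- genome_unique_km1(300, k, seed = 2)
  mid <- 150
  x <- substr(trunk, mid, mid + k - 1)
  # spur: one alternative extension followed by a short dead end
  true_next <- substr(trunk, mid + k, mid + k)
  spur_base <- setdiff(c("A", "C", "G", "T"), true_next)[1]
  spur_seq <- paste0(substr(trunk, mid + 1, mid + k - 1), spur_base, "A")
  # spur_seq has 2 k-mers: a 2-node spur, well under depth k
  f <- exactish_filter(c(trunk, spur_seq), k)
  g <- dbg(f, k)
  cl <- lookahead_classify(g, x)
  expect_identical(cl$kind, "false_branch_pruned")
  expect_identical(cl$surviving, true_next)
  expect_equal(cl$n_raw, 2)

  # a second long branch halts extension
  branch2 <- paste0(substr(trunk, mid + 1, mid + k - 1), spur_base,
                    substr(genome_unique_km1(60, k, seed = 9), 1, 40))
  f2 <- exactish_filter(c(trunk, branch2), k)
  cl2 <- lookahead_classify(dbg(f2, k), x)
  expect_identical(cl2$kind, "true_branch")
  expect_setequal(cl2$surviving, c(true_next, spur_base))

  # no candidate extensions at the trunk end
  last <- substr(trunk, nchar(trunk) - k + 1, nchar(trunk))
  expect_identical(lookahead_classify(g, last)$kind, "dead_end")
})

test_that("look-ahead never prunes an extension on a path longer than
           depth (breadth-first oracle)", {
  k <- 9
  set.seed(13)
  trunk <- genome_unique_km1(200, k, seed = 21)
  # branches of varying length hanging off one point
  mid <- 100
  x <- substr(trunk, mid, mid + k - 1)
  true_next <- substr(trunk, mid + k, mid + k)
  alt <- setdiff(c("A", "C", "G", "T"), true_next)
  for (extra in c(3, k, k + 1, 2 * k)) {
    branch <- paste0(substr(trunk, mid + 1, mid + k - 1), alt[1],
                     random_dna(extra - 1))
    f <- exactish_filter(c(trunk, branch), k)
    g <- dbg(f, k)
    cl <- lookahead_classify(g, x)
    # breadth-first survival oracle over raw successor queries
    bfs_survives <- function(kmer) {
      frontier <- kmer
      for (step in seq_len(k)) {
        frontier <- unique(unlist(lapply(frontier, function(z) {
          names(dbg_successors(g, z))
        })))
        if (length(frontier) == 0) return(FALSE)
      }
      TRUE
    }
    raw <- names(dbg_successors(g, x))
    surv_oracle <- vapply(raw, bfs_survives, TRUE)
    expect_setequal(cl$surviving,
                    substr(raw[surv_oracle], k, k))
  }
})
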