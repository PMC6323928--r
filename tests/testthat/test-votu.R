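test_that("ANI identities: self, reverse complement, containment", {
  set.seed(3)
  a <- random_dna(800)
  r <- pairwise_ani(a, a)
  expect_equal(r$ani_pct, 100)
  expect_equal(r$af_pct, 100)

  r <- pairwise_ani(a, revcomp_of(a))
  expect_equal(r$ani_pct, 100)
  expect_equal(r$af_pct, 100)

  # the shorter sequence is fully contained, so AF (of the shorter) is 100
  r <- pairwise_ani(a, substr(a, 1, 400))
  expect_equal(r$ani_pct, 100)
  expect_equal(r$af_pct, 100)

  expect_error(pairwise_ani(a, ""), "non-empty")
})

test_that("ANI recovers a known substitution fraction", {
  set.seed(4)
  a <- random_dna(1000)
  b <- mutate_to_identity(a, 90, 99)
  # ground truth from the substitution mask: exactly 100 mismatches
  ca <- chars_of(a); cb <- chars_of(b)
  expect_equal(sum(ca != cb), 100L)
  r <- pairwise_ani(a, b)
  expect_lt(abs(r$ani_pct - 90), 1)
  expect_gte(r$af_pct, 99)
})

test_that("pairwise_ani is symmetric in its arguments", {
  set.seed(5)
  for (k in 1:4) {
    a <- random_dna(sample(300:700, 1))
    b <- if (k %% 2 == 0) mutate_to_identity(a, 92, k) else random_dna(500)
    expect_identical(pairwise_ani(a, b), pairwise_ani(b, a))
  }
})

test_that("single linkage chains clusters through intermediate members", {
  set.seed(6)
  a <- random_dna(1500)
  b <- mutate_to_identity(a, 97, 21)       # a-b ~97%
  c <- mutate_to_identity(b, 96.5, 22)     # b-c ~96.5%, a-c ~93.6%
  seqs <- c(A = a, B = b, C = c)
  tab <- pairwise_ani_table(seqs)
  ac <- tab$ani_pct[tab$id1 == "A" & tab$id2 == "C"]
  expect_lt(ac, 95)                         # a-c alone would not link
  v <- build_votus(seqs, ani_table = tab)
  df <- as.data.frame(v)
  expect_equal(unique(df$votu_name), "vc_1")
  expect_equal(sort(df$seq_id), c("A", "B", "C"))
})

test_that("identical sequences form one vc_ cluster; unrelated ones are sg_", {
  set.seed(7)
  s <- random_dna(600)
  v <- build_votus(c(x1 = s, x2 = s, x3 = s))
  expect_equal(length(v), 1L)
  expect_equal(v[[1]]$name, "vc_1")
  expect_length(v[[1]]$member_ids, 3L)

  seqs <- c(u1 = random_dna(600), u2 = random_dna(600),
            u3 = random_dna(600), u4 = random_dna(600))
  v <- build_votus(seqs)
  df <- as.data.frame(v)
  expect_equal(sort(df$votu_name), paste0("sg_", 1:4))
  expect_equal(df$n_members, rep(1L, 4))
})

test_that("vOTUs partition the input and naming is deterministic", {
  set.seed(8)
  base1 <- random_dna(700)
  base2 <- random_dna(700)
  seqs <- c(a1 = base1, a2 = mutate_to_identity(base1, 98, 1),
            b1 = base2, b2 = mutate_to_identity(base2, 98, 2),
            b3 = mutate_to_identity(base2, 97, 3),
            solo = random_dna(700))
  tab <- pairwise_ani_table(seqs)
  v <- build_votus(seqs, ani_table = tab)
  df <- as.data.frame(v)
  expect_setequal(df$seq_id, names(seqs))
  expect_equal(anyDuplicated(df$seq_id), 0L)
  # larger cluster named first
  expect_equal(df$votu_name[df$seq_id == "b1"], "vc_1")
  expect_equal(df$votu_name[df$seq_id == "a1"], "vc_2")
  expect_equal(df$votu_name[df$seq_id == "solo"], "sg_1")
  # determinism on the cached table
  expect_identical(as.data.frame(build_votus(seqs, ani_table = tab)), df)
})

test_that("raising the ANI threshold never decreases the cluster count", {
  set.seed(9)
  base <- random_dna(800)
  seqs <- c(s1 = base, s2 = mutate_to_identity(base, 97, 4),
            s3 = mutate_to_identity(base, 93, 5),
            s4 = random_dna(800))
  tab <- pairwise_ani_table(seqs)
  n_prev <- 0L
  for (thr in c(90, 94, 96, 99.5)) {
    v <- build_votus(seqs, clustering_params(min_ani_pct = thr),
                     ani_table = tab)
    expect_gte(length(v), n_prev)
    n_prev <- length(v)
  }
})

test_that("adding a sequence can merge but never split clusters", {
  set.seed(10)
  base <- random_dna(700)
  seqs <- c(p1 = base, p2 = mutate_to_identity(base, 96, 6),
            q1 = random_dna(700), q2 = random_dna(700))
  bridge <- c(seqs, bridge = mutate_to_identity(base, 97, 7))
  before <- build_votus(seqs)
  after <- build_votus(bridge)
  after_sets <- lapply(after, `[[`, "member_ids")
  for (cl in before) {
    containing <- vapply(after_sets, function(m) all(cl$member_ids %in% m),
                         logical(1))
    expect_true(any(containing))
  }
})
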