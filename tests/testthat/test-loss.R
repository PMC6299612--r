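quartet <- read_newick("((A,B),(C,D));")

test_that("Dollo loss counting matches the forced examples", {
  r0 <- dollo_losses(quartet, c("A", "B", "C", "D"))
  expect_equal(r0$loss_count, 0L)

  r1 <- dollo_losses(quartet, c("A", "B"), origin_mode = "mrca")
  expect_equal(r1$loss_count, 0L)
  r2 <- dollo_losses(quartet, c("A", "B"), origin_mode = "root")
  expect_equal(r2$loss_count, 1L)
  expect_setequal(r2$loss_branches[[1]], c("C", "D"))

  r3 <- dollo_losses(quartet, c("A", "C"))
  expect_equal(r3$loss_count, 2L)
  expect_setequal(unlist(r3$loss_branches), c("B", "D"))

  expect_error(dollo_losses(quartet, character()), "no present tips")
})

test_that("unknown tips follow the configured policy", {
  states <- c(A = "present", B = "unknown", C = "absent", D = "absent")
  ex <- dollo_losses(quartet, states, origin_mode = "root")
  expect_equal(ex$unknown_tips, "B")
  expect_equal(ex$loss_count, 1L)  # B dropped; losses = (C,D) clade
  ab <- dollo_losses(quartet, states, origin_mode = "root",
                     unknown = "absent")
  expect_equal(ab$loss_count, 2L)  # B and the (C,D) clade
  pr <- dollo_losses(quartet, states, origin_mode = "root",
                     unknown = "present")
  expect_equal(pr$loss_count, 1L)
})

test_that("the packaged eukaryote dataset implies 15 and 18 losses", {
  dat <- example_gainloss_data()
  st <- dollo_losses(dat$tree, presence_column(dat$presence, "ST"),
                     origin_mode = "root", family = "ST")
  aq <- dollo_losses(dat$tree, presence_column(dat$presence, "Aquatic"),
                     origin_mode = "root", family = "Aquatic")
  expect_equal(st$loss_count, 15L)
  expect_equal(aq$loss_count, 18L)
  # loss branches are disjoint, maximal, and exclude present tips
  for (rep in list(st, aq)) {
    lost <- unlist(rep$loss_branches)
    expect_equal(anyDuplicated(lost), 0L)
    expect_length(intersect(lost, rep$present_tips), 0L)
  }
})

test_that("minimum-cost histories match the forced examples", {
  h1 <- min_cost_history(quartet, c("A", "C"), gain_cost = 1, loss_cost = 1)
  expect_equal(h1$total_cost, 2)
  expect_equal(h1$n_gains, 2L)
  expect_equal(h1$n_losses, 0L)
  expect_equal(h1$root_state, "absent")

  h2 <- min_cost_history(quartet, c("A", "C"), gain_cost = 10, loss_cost = 1)
  expect_equal(h2$total_cost, 12)  # one origin gain + two losses
  expect_equal(h2$n_gains, 1L)
  expect_equal(h2$n_losses, 2L)
  expect_equal(h2$root_state, "present")

  # infinite gain cost reproduces the Dollo count exactly
  dat <- example_gainloss_data()
  for (fam in c("ST", "Aquatic")) {
    col <- presence_column(dat$presence, fam)
    dol <- dollo_losses(dat$tree, col, origin_mode = "root")
    inf <- min_cost_history(dat$tree, col, gain_cost = Inf, loss_cost = 1)
    expect_equal(inf$n_losses, dol$loss_count)
    expect_equal(inf$n_gains, 1L)
    expect_equal(inf$total_cost, dol$loss_count)
  }
  expect_error(min_cost_history(quartet, c(A = "unknown", B = "unknown",
                                           C = "unknown", D = "unknown")),
               "unknown")
})

test_that("scenario tables sweep the gain/loss trade-off monotonically", {
  tab <- scenario_table(quartet, c("A", "C"), gain_costs = c(1, 1.5, 3, 10))
  expect_true(tab$dollo[nrow(tab)])
  # gains drop from 2 to 1 as the ratio crosses 2
  expect_equal(tab$n_gains[tab$gain_cost == 1], 2L)
  expect_equal(tab$n_gains[tab$gain_cost == 3], 1L)
  expect_true(all(diff(tab$n_gains) <= 0))
  # all-present column: always a single origin, no losses
  tab2 <- scenario_table(quartet, c("A", "B", "C", "D"),
                         gain_costs = c(1, 5))
  expect_true(all(tab2$n_gains == 1L))
  expect_true(all(tab2$n_losses == 0L))
  # packaged dataset, Dollo row
  dat <- example_gainloss_data()
  tab3 <- scenario_table(dat$tree, presence_column(dat$presence, "ST"),
                         gain_costs = 2)
  expect_equal(tab3$n_losses[tab3$dollo], 15L)
})

test_that("monophyly testing reports the smallest containing clade", {
  m1 <- is_monophyletic(quartet, c("A", "B"))
  expect_true(m1$monophyletic)
  expect_equal(m1$clade_size, 2L)
  m2 <- is_monophyletic(quartet, c("A", "C"))
  expect_false(m2$monophyletic)
  expect_equal(m2$clade_size, 4L)
  m3 <- is_monophyletic(quartet, "A")
  expect_true(m3$monophyletic)
  expect_error(is_monophyletic(quartet, c("A", "Z")), "unknown tip.*Z")
})

test_that("absent outgroup tips never change mrca-mode loss counts", {
  for (i in 1:10) {
    tree <- random_tree(sample(5:10, 1), seed = 700 + i)
    tips <- tree$tip.label
    present <- sample(tips, sample(2:(length(tips) - 1), 1))
    base <- dollo_losses(tree, present, origin_mode = "mrca")
    # attach a new absent tip as sister to everything (outside the origin)
    s <- write_newick(tree)
    grown <- read_newick(paste0("(", sub(";$", "", s), ",OUT);"))
    added <- dollo_losses(grown, present, origin_mode = "mrca")
    expect_equal(added$loss_count, base$loss_count, info = paste("rep", i))
  }
})

test_that("polytomies count sibling losses independently", {
  star <- read_newick("(A,B,C,D,E);")
  r <- dollo_losses(star, c("A"), origin_mode = "root")
  expect_equal(r$loss_count, 4L)
  h <- min_cost_history(star, c("A", "B"), gain_cost = 10, loss_cost = 1)
  expect_equal(h$total_cost, 13)  # origin + three losses
})
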