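test_that("pool correction filters species and read tables", {
  pool <- c("Aa s1", "Cc s3", "Ee s5")
  expect_equal(correct_to_pool(c("Aa s1", "Bb s2", "Cc s3", "Dd s4"), pool),
               c("Aa s1", "Cc s3"))
  expect_equal(correct_to_pool(c("Aa s1"), c("Aa s1", "Bb s2")), "Aa s1")
  expect_length(correct_to_pool(c("Xx s9"), pool), 0)
  tab <- tiny_read_table()
  kept <- correct_to_pool(tab, c("Salmo trutta"))
  expect_equal(kept$species, "Salmo trutta")
  empty <- correct_to_pool(tab, c("Esox lucius"))
  expect_equal(nrow(empty), 0)
  expect_equal(richness_per_site(empty)$richness, c(0L, 0L))
})

test_that("per-site richness counts positive entries", {
  tab <- as_read_table(tibble::tibble(
    species = c("Aa s1", "Bb s2", "Cc s3"),
    S01 = c(10L, 0L, 3L), S02 = c(0L, 0L, 0L)
  ))
  expect_equal(richness_per_site(tab)$richness, c(2L, 0L))
  # correction can only reduce richness
  pool <- c("Aa s1")
  r_before <- richness_per_site(tab)$richness
  r_after <- richness_per_site(correct_to_pool(tab, pool))$richness
  expect_true(all(r_after <= r_before))
})

test_that("four-category classification matches set enumeration", {
  pool <- c("A a", "B b", "C c", "D d", "E e")
  part <- classify_species(original = c("A a", "B b", "C c"),
                           reanalyzed_basin = c("B b", "C c", "D d"),
                           basin_pool = pool)
  expect_equal(part$shared, c("B b", "C c"))
  expect_equal(part$unique_reanalysis, "D d")
  expect_equal(part$unique_original_local, "A a")
  expect_length(part$unique_original_nonlocal, 0)

  same <- classify_species(c("A a", "B b"), c("A a", "B b"), pool)
  expect_equal(same$shared, c("A a", "B b"))
  expect_true(all(lengths(same[-1]) == 0))

  off <- classify_species("X x", character(), pool)
  expect_equal(off$unique_original_nonlocal, "X x")
  expect_true(all(lengths(off[-4]) == 0))

  expect_error(classify_species("A a", "Z z", pool), "outside the basin pool")
})

test_that("partition identity holds on random set triples", {
  set.seed(202)
  universe <- sprintf("G%02d s%02d", rep(1:12, each = 12), 1:144)
  for (i in 1:200) {
    pool <- sample(universe, sample(20:60, 1))
    rean <- sample(pool, sample(0:15, 1))
    orig <- sample(universe, sample(0:30, 1))
    part <- classify_species(orig, rean, pool)
    expect_equal(sum(lengths(part)), length(union(orig, rean)))
    all_sp <- unlist(part)
    expect_false(anyDuplicated(all_sp) > 0)
    expect_setequal(all_sp, union(orig, rean))
  }
})

test_that("shared-species and shared-read proportions match hand sums", {
  part <- classify_species(c("A a", "B b", "C c"), c("B b", "C c", "D d"),
                           c("A a", "B b", "C c", "D d"))
  expect_equal(prop_shared_species(part), 2 / 3)
  expect_equal(prop_shared_species(classify_species("A a", "A a", "A a")), 1)
  disjoint <- classify_species("A a", "B b", c("A a", "B b"))
  expect_equal(prop_shared_species(disjoint), 0)
  expect_error(prop_shared_species(classify_species("X x", character(), "A a")),
               "undefined")

  tab <- as_read_table(tibble::tibble(
    species = c("B b", "C c", "D d"),
    S01 = c(30L, 20L, 10L), S02 = c(15L, 5L, 20L)
  ))
  expect_equal(prop_shared_reads(tab, c("B b", "C c")), 70 / 100)
  expect_equal(prop_shared_reads(tab, tab$species), 1)
  expect_equal(prop_shared_reads(tab, character()), 0)
})

test_that("abundance indices match hand computations and normalize", {
  tab <- tiny_read_table()  # sites (A=10,B=30), (A=20,B=40)
  a <- species_total_relabund(tab)
  expect_equal(a$a[a$species == "Salmo trutta"], 0.3)
  expect_equal(a$a[a$species == "Barbus barbus"], 0.7)
  b <- species_mean_site_relabund(tab)
  expect_equal(b$b[b$species == "Salmo trutta"], (0.25 + 1 / 3) / 2,
               tolerance = 1e-12)
  expect_equal(b$b[b$species == "Barbus barbus"], (0.75 + 2 / 3) / 2,
               tolerance = 1e-12)

  single <- as_read_table(tibble::tibble(species = "A a", S01 = 5L))
  expect_equal(species_total_relabund(single)$a, 1)
  expect_equal(species_mean_site_relabund(single)$b, 1)

  set.seed(33)
  for (i in 1:50) {
    rt <- random_read_table()
    expect_equal(sum(species_total_relabund(rt)$a), 1, tolerance = 1e-12)
    expect_equal(sum(species_mean_site_relabund(rt)$b), 1, tolerance = 1e-12)
  }
})

test_that("zero-total sites are dropped from the b index", {
  tab <- as_read_table(tibble::tibble(
    species = c("A a", "B b"),
    S01 = c(3L, 1L), S02 = c(0L, 0L), S03 = c(1L, 1L)
  ))
  b <- species_mean_site_relabund(tab)
  expect_equal(b$b, c((0.75 + 0.5) / 2, (0.25 + 0.5) / 2))
  allzero <- as_read_table(tibble::tibble(species = "A a", S01 = 0L))
  expect_error(species_mean_site_relabund(allzero), "zero")
  expect_error(species_total_relabund(allzero), "zero")
})

test_that("p_read equals the sum of a over shared species", {
  set.seed(44)
  for (i in 1:50) {
    rt <- random_read_table()
    shared <- sample(rt$species, sample(0:nrow(rt), 1))
    a <- species_total_relabund(rt)
    expect_equal(prop_shared_reads(rt, shared),
                 sum(a$a[a$species %in% shared]), tolerance = 1e-12)
  }
})

test_that("extra-local barcode counts are bounded intersections", {
  refdb <- c("A a", "B b", "C c")
  expect_equal(extra_local_barcode_count(character(), refdb), 0)
  cat3 <- c("A a", "B b", "X x", "Y y", "Z z")
  expect_equal(extra_local_barcode_count(cat3, refdb), 2)
  expect_lte(extra_local_barcode_count(cat3, refdb), length(cat3))
})

test_that("congruence report reproduces truth-level shared species", {
  col <- small_collection(seed = 52, n_datasets = 10)
  cr <- suppressWarnings(congruence_report(col))
  for (i in seq_len(nrow(cr))) {
    tr <- col$truth$datasets[[which(
      vapply(col$truth$datasets, `[[`, "", "dataset_id") == cr$dataset_id[i])]]
    # shared species recorded in truth that the table detected are recovered
    expect_equal(cr$n_shared[i], length(tr$shared))
  }
  expect_true(all(cr$p_sp >= 0 & cr$p_sp <= 1, na.rm = TRUE))
  expect_true(all(cr$extra_local_with_barcode <= cr$n_unique_orig_local))
})

test_that("corrected species totals are monotone over nested scales", {
  col <- small_collection(seed = 53, n_datasets = 12)
  st <- species_totals(col)
  n <- setNames(st$n_species, st$scale)
  expect_lte(n[["basin"]], n[["country"]])
  expect_lte(n[["country"]], n[["continent"]])
  expect_lte(n[["continent"]], n[["global"]])
})
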