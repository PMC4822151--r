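toy_cells <- function() {
  data.frame(
    animal = rep(c("a1", "a2"), each = 4),
    region = "LV",
    nuclearity = c(1, 1, 2, 2, 1, 2, 2, 2),
    volume_um3 = c(100, 120, 200, 220, 130, 210, 230, 250),
    excluded = FALSE)
}

test_that("summaries aggregate per animal first, then across animals", {
  s <- summarize_cells(toy_cells())
  expect_s3_class(s, "GroupSummary")
  mono <- s$nuclearity[s$nuclearity$nuclearity_class == "mono", ]
  bi <- s$nuclearity[s$nuclearity$nuclearity_class == "bi", ]
  # animal a1: 50% mono, mean 110; animal a2: 25% mono, mean 130
  expect_equal(mono$pct_mean, mean(c(50, 25)))
  expect_equal(mono$pct_sd, sd(c(50, 25)))
  expect_equal(mono$volume_mean, mean(c(110, 130)))
  expect_equal(mono$volume_sd, sd(c(110, 130)))
  expect_equal(mono$n_cells, 3)
  expect_equal(bi$volume_mean, mean(c(210, 230)))
  expect_equal(bi$n_animals, 2)
  expect_false(any(s$nuclearity$single_animal))
  expect_match(s$meta$dispersion, "SD")
})

test_that("excluded cells are dropped and missing columns error", {
  cells <- toy_cells()
  cells$excluded[cells$animal == "a2"] <- TRUE
  s <- summarize_cells(cells)
  expect_true(all(s$nuclearity$n_animals == 1))
  expect_true(all(s$nuclearity$single_animal))
  expect_error(summarize_cells(toy_cells()[, -1]), class = "missing_column")
})

test_that("ploidy percentages are summarised per nuclearity class", {
  cells <- toy_cells()
  cells$ploidy_label <- c("2n", "2n", "2*2n", "2*4n",
                          "2n", "2*2n", "2*2n", "2*2n")
  s <- summarize_cells(cells)
  bi22 <- s$ploidy[s$ploidy$nuclearity_class == "bi" &
                     s$ploidy$ploidy_label == "2*2n", ]
  # a1: 1/2 of bi cells are 2*2n; a2: 3/3
  expect_equal(bi22$pct_mean, mean(c(50, 100)))
})

test_that("percent volume difference is the published statistic", {
  expect_equal(percent_volume_difference(8007, 5634), 42.1)
  expect_equal(percent_volume_difference(210, 140), 50)
  expect_error(percent_volume_difference(100, 0), class = "invalid_volume")
  expect_error(percent_volume_difference(-1, 100), class = "invalid_volume")
})

test_that("the bundled reference volume table is well formed", {
  pub <- published_group_volumes()
  expect_equal(nrow(pub), 10)
  expect_true(all(c("species", "age", "region", "mono_volume_um3",
                    "bi_volume_um3", "published_percent_larger") %in%
                    names(pub)))
  expect_true(all(pub$bi_volume_um3 > pub$mono_volume_um3))
})
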