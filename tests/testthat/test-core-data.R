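test_that("recall loading round-trips well-formed files and reports bad rows", {
    f <- writeRecords(toyRecords())
    rec <- loadRecalls(f)
    expect_equal(nrow(rec), 3L)
    expect_equal(rec$amount_g, c(120, 30, 200))

    df <- toyRecords()
    df$amount_g <- NULL
    expect_error(loadRecalls(writeRecords(df)), "amount_g")

    df <- toyRecords()
    df$amount_g[2L] <- -1
    expect_warning(rec <- loadRecalls(writeRecords(df)), "2")
    expect_equal(nrow(rec), 2L)
    expect_equal(attr(rec, "rejected"), 2L)
})

test_that("energy plausibility excludes <600 kcal and flags >4500 kcal", {
    rec <- data.frame(
        participant_id = rep(c("P1", "P2", "P3"), each = 2L),
        recall_id = rep(c("R1", "R2", "R3"), each = 2L),
        trimester = 1L, occasion_index = 1L, occasion_label = "lunch",
        food_code = "X",
        amount_g = 100,
        energy_kcal = c(275, 275,     # 550 total  -> excluded
                        2300, 2300,   # 4600 total -> retained + flagged
                        1000, 1000),  # 2000 total -> retained, unflagged
        stringsAsFactors = FALSE)
    out <- filterEnergyPlausibility(rec)
    expect_setequal(unique(out$excluded$recall_id), "R1")
    expect_setequal(unique(out$retained$recall_id), c("R2", "R3"))
    expect_equal(out$flagged, "R2")
    expect_equal(out$totals$status[out$totals$recall_id == "R3"],
                 "retained")
    # boundary: exactly 600 retained, exactly 4500 not flagged
    rec$energy_kcal <- c(300, 300, 2250, 2250, 1000, 1000)
    out <- filterEnergyPlausibility(rec)
    expect_equal(nrow(out$excluded), 0L)
    expect_length(out$flagged, 0L)
})

test_that("occasion labels map onto the four network meal types", {
    expect_equal(normalizeMealType("supper", quiet = TRUE), "dinner")
    expect_equal(normalizeMealType("breakfast", quiet = TRUE), "breakfast")
    expect_true(is.na(normalizeMealType("just_a_supplement", quiet = TRUE)))
    expect_equal(normalizeMealType(c("brunch", "just_a_drink"),
                                   quiet = TRUE), c("lunch", "snack"))
    expect_equal(normalizeMealType("brunch",
                                   policy = list(brunch = "breakfast"),
                                   quiet = TRUE), "breakfast")
    expect_error(normalizeMealType("elevenses", quiet = TRUE), "elevenses")
    expect_message(normalizeMealType("supper"), "dinner")
})

test_that("meal matrix aggregates items per occasion with zero columns kept", {
    tax <- makeTaxonomy(c(M1 = "milk", C1 = "cereal", F1 = "fruit"))
    rec <- data.frame(
        participant_id = "P1", recall_id = "R1", trimester = 1L,
        occasion_index = c(1L, 1L, 1L),
        occasion_label = "breakfast",
        food_code = c("M1", "C1", "M1"),
        amount_g = c(100, 30, 50), energy_kcal = c(60, 110, 30),
        stringsAsFactors = FALSE)
    me <- buildMealMatrix(rec, tax)
    expect_s4_class(me, "MealExperiment")
    X <- mealMatrix(me)
    expect_equal(dim(X), c(1L, 3L))
    expect_equal(X[1L, "milk"], 150)     # two milk items summed
    expect_equal(X[1L, "cereal"], 30)
    expect_equal(X[1L, "fruit"], 0)      # never consumed, still a column

    expect_error(buildMealMatrix(transform(rec, food_code = "ZZ"), tax),
                 "ZZ")
    expect_message(
        me2 <- buildMealMatrix(transform(rec, food_code = c("M1", "ZZ",
                                                            "M1")),
                               tax, unmapped = "drop"), "ZZ")
    expect_equal(mealMatrix(me2)[1L, "milk"], 150)
})

test_that("meal matrix construction is additive over record batches", {
    cfg <- defaultGeneratorConfig(nParticipants = 6L, nGroups = 8L)
    co <- simulateCohort(7L, cfg)
    rec <- co$records
    rec <- rec[rec$occasion_label != "just_a_supplement", ]
    half <- seq_len(nrow(rec)) %% 2L == 0L
    one <- mealMatrix(buildMealMatrix(rec, co$taxonomy))
    a <- mealMatrix(buildMealMatrix(rec[half, ], co$taxonomy))
    b <- mealMatrix(buildMealMatrix(rec[!half, ], co$taxonomy))
    combined <- matrix(0, nrow(one), ncol(one), dimnames = dimnames(one))
    combined[rownames(a), ] <- combined[rownames(a), ] + a
    combined[rownames(b), ] <- combined[rownames(b), ] + b
    expect_equal(one, combined)
})

test_that("prevalence filter uses strict fewer-than semantics and is idempotent", {
    X <- matrix(0, 40L, 5L,
                dimnames = list(NULL, paste0("g", 1:5)))
    X[1:2, 1L] <- 1          # 2/40 = 5%  -> retained (boundary)
    X[1L, 2L] <- 1           # 1/40 = 2.5% -> excluded
    X[1:10, 3L] <- 1         # 25%         -> retained
    X[, 4L] <- 1             # 100%        -> retained
    me <- mealsFromMatrix(X)           # column 5 all zero -> excluded
    out <- prevalenceFilter(me)
    expect_setequal(rownames(out), c("g1", "g3", "g4"))
    expect_setequal(S4Vectors::metadata(out)$excluded_groups,
                    c("g2", "g5"))
    again <- prevalenceFilter(out)
    expect_equal(rownames(again), rownames(out))
    expect_length(S4Vectors::metadata(again)$excluded_groups, 0L)
    expect_error(prevalenceFilter(me[, integer(0)]), "empty")
})
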