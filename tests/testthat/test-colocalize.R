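# Distance-threshold co-localization and subpopulation classification.

test_that("the 3-px distance rule splits pairs exactly at the radius", {
    one <- matchChannels(list(CD9 = spotsAt(10, 10)))
    expect_equal(nrow(records(one)), 1)
    expect_equal(records(one)$class, "CD9")

    near <- matchChannels(list(CD9 = spotsAt(10, 10),
                               CD63 = spotsAt(11, 12)))   # sqrt(5) ~ 2.24
    expect_equal(nrow(records(near)), 1)
    expect_equal(records(near)$n_labels, 2)
    expect_equal(records(near)$class, paste0("CD9", DOT, "CD63"))
    expect_equal(records(near)$max_pair_distance, sqrt(5))

    far <- matchChannels(list(CD9 = spotsAt(10, 10),
                              CD63 = spotsAt(12, 13)))    # sqrt(13) > 3
    expect_equal(nrow(records(far)), 2)
    expect_true(all(records(far)$n_labels == 1))

    expect_error(matchChannels(list(CD9 = spotsAt(1, 1),
                                    CD9 = spotsAt(2, 2))), "unique")
})

test_that("classification is canonical and spans exactly seven classes", {
    expect_equal(canonicalClass("CD63", CH3), "CD63")
    expect_equal(canonicalClass(c("CD81", "CD9"), CH3),
                 paste0("CD9", DOT, "CD81"))
    expect_error(canonicalClass(character(), CH3), "empty")
    expect_error(canonicalClass("CD7", CH3), "not in")
    cls <- allClasses(CH3)
    expect_length(cls, 7)
    expect_equal(anyDuplicated(cls), 0)
    # every simulated record maps into the 7-class space
    spec <- hek293Spec(500)
    truth <- generatePopulation(spec, smallParams(), seed = 5)
    expect_true(all(truth$class %in% cls))
})

test_that("every spot lands in exactly one record (partition property)", {
    set.seed(91)
    for (rep in 1:20) {
        sp <- lapply(CH3, function(ch) {
            n <- sample(0:10, 1)
            s <- spotsAt(runif(n, 0, 20), runif(n, 0, 20))
            s$uid <- if (n > 0) paste0(ch, seq_len(n)) else character()
            s
        })
        names(sp) <- CH3
        vs <- matchChannels(sp)
        nIn <- sum(vapply(sp, nrow, integer(1)))
        expect_equal(nrow(spotTable(vs)), nIn)
        expect_equal(sum(records(vs)$n_spots), nIn)
        expect_equal(anyDuplicated(spotTable(vs)$uid), 0)
        # chain bound under component semantics
        expect_true(all(records(vs)$max_pair_distance <= 2 * 3 + 1e-9))
    }
})

test_that("channel relabelling permutes class names but not the partition", {
    set.seed(92)
    sp <- lapply(CH3, function(ch) {
        s <- spotsAt(runif(6, 0, 15), runif(6, 0, 15))
        s$uid <- paste0(ch, 1:6)
        s
    })
    names(sp) <- CH3
    vs1 <- matchChannels(sp)
    vs2 <- matchChannels(sp[c("CD81", "CD9", "CD63")])
    expect_equal(vesicleSetPartition(vs1), vesicleSetPartition(vs2))
    f1 <- colocalizationFraction(vs1)
    f2 <- colocalizationFraction(vs2)
    expect_equal(f1$recordFraction, f2$recordFraction)
    expect_equal(f1$signalFraction, f2$signalFraction)
})

test_that("multi-label records are monotone in the threshold", {
    set.seed(93)
    sp <- lapply(CH3, function(ch)
        spotsAt(runif(40, 0, 60), runif(40, 0, 60)))
    names(sp) <- CH3
    nMulti <- vapply(c(0.5, 1, 2, 3, 5, 8), function(thr) {
        vs <- matchChannels(sp, colocalizationParams(thresholdPx = thr))
        sum(records(vs)$n_labels >= 2)
    }, numeric(1))
    expect_true(all(diff(nMulti) >= 0))
})

test_that("greedy matching is optimal in the separated regime", {
    r <- 3
    set.seed(94)
    for (rep in 1:100) {
        # true pairs <= r/2 apart, impostors > 2r away: grid layout
        nTrue <- sample(1:3, 1)
        centres <- data.frame(x = 10 + 8 * seq_len(nTrue), y = 10)
        sp <- list()
        for (ci in 1:2) {
            off <- runif(nTrue, -r / 4, r / 4)
            sp[[ci]] <- data.frame(x = centres$x + off,
                                   y = centres$y + off,
                                   ch = ci)
        }
        spots <- do.call(rbind, sp)
        oracle <- bruteMatchPartition(spots, r)
        byCh <- split(spots, spots$ch)
        input <- lapply(byCh, function(s) {
            s$uid <- rownames(s)
            s
        })
        names(input) <- c("A", "B")
        vs <- matchChannels(input, colocalizationParams(thresholdPx = r))
        sp2 <- spotTable(vs)
        got <- partitionKey(sp2$record_id[order(match(sp2$uid,
                                                      rownames(spots)))])
        expect_equal(got, oracle$partition)
    }
})

test_that("record- and signal-level co-localized fractions are computed", {
    vs <- matchChannels(list(CD9 = spotsAt(c(10, 40), c(10, 40)),
                             CD63 = spotsAt(10.5, 10.5),
                             CD81 = spotsAt(10.2, 10.8)))
    expect_equal(nrow(records(vs)), 2)
    fr <- colocalizationFraction(vs)
    expect_equal(fr$recordFraction, 0.5)
    expect_equal(fr$signalFraction, 0.75)

    singles <- matchChannels(list(CD9 = spotsAt(10, 10),
                                  CD63 = spotsAt(50, 50)))
    frS <- colocalizationFraction(singles)
    expect_equal(frS$recordFraction, 0)
    expect_equal(frS$signalFraction, 0)

    empty <- matchChannels(list(CD9 = spotsAt(numeric(), numeric())))
    expect_error(colocalizationFraction(empty), "undefined")
})

test_that("clique semantics splits chains that component semantics keeps", {
    sp <- list(CD9 = spotsAt(0, 10), CD63 = spotsAt(2.8, 10),
               CD81 = spotsAt(5.6, 10))
    comp <- matchChannels(sp, colocalizationParams(semantics = "component"))
    expect_equal(nrow(records(comp)), 1)
    expect_equal(records(comp)$n_labels, 3)
    expect_equal(records(comp)$max_pair_distance, 5.6)

    clq <- matchChannels(sp, colocalizationParams(semantics = "clique"))
    expect_equal(nrow(records(clq)), 2)
    expect_true(all(records(clq)$max_pair_distance <= 3))
})
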