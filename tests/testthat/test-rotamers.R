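tmpl <- buildFragment(3.0, 60, -90, 1.8)
rmap <- syntheticRoleMap()

test_that("setDihedral reaches the target and moves only the moving set", {
    f2 <- setDihedral(tmpl, chi1Quad(), -90, chi1Moving())
    r <- resolveRoles(f2, rmap)
    expect_lt(abs(measureDihedral(r$C50$xyz, r$N99$xyz, r$CA$xyz,
                                  r$C80$xyz) - (-90)), 1e-6)

    f3 <- setDihedral(tmpl, chi1Quad(), 45, chi1Moving())
    r3 <- resolveRoles(f3, rmap)
    expect_lt(abs(measureDihedral(r3$C50$xyz, r3$N99$xyz, r3$CA$xyz,
                                  r3$C80$xyz) - 45), 1e-6)
    fixedIdx <- which(!atoms(tmpl)$name %in%
                      c("C80", "H99", "CB", "CG", "CD", "CAD"))
    expect_identical(coords(f3)[fixedIdx, ], coords(tmpl)[fixedIdx, ])

    # setting to the current value leaves every coordinate untouched
    f4 <- setDihedral(tmpl, chi1Quad(), -90, chi1Moving())
    f5 <- setDihedral(f4, chi1Quad(), -90, chi1Moving())
    expect_lt(max(abs(coords(f5) - coords(f4))), 1e-9)

    expect_error(
        setDihedral(tmpl, chi1Quad(), -90,
                    c(chi1Moving(), list(selALD("C3"))),
                    anchorSet = list(selALD("C3"), selALD("C50"))),
        "anchor violation")
})

test_that("candidate generation fixes the anchor and respects bounds", {
    spec <- rotamerSpec(nCandidates = 10L, libraryCap = 10L, seed = 99L)
    cand <- generateCandidates(tmpl, spec)
    expect_length(cand, 10L)
    anchorIdx <- vapply(resolveRoles(tmpl, rmap)$PLP_ANCHOR_SET,
                        `[[`, integer(1), "index")
    for (fr in cand)
        expect_identical(coords(fr)[anchorIdx, ], coords(tmpl)[anchorIdx, ])

    # chi1 untouched; perturbed dihedrals within +/- 30 deg of template
    dihVal <- function(fr, nms) {
        idx <- match(nms, atoms(fr)$name)
        measureDihedral(coords(fr)[idx[1], ], coords(fr)[idx[2], ],
                        coords(fr)[idx[3], ], coords(fr)[idx[4], ])
    }
    for (fr in cand) {
        expect_lt(abs(dihVal(fr, c("C50", "N99", "CA", "C80")) - (-90)), 1e-6)
        for (q in list(c("N99", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
                       c("CB", "CG", "CD", "CAD"))) {
            dTempl <- dihVal(tmpl, q)
            dd <- dihVal(fr, q) - dTempl
            dd <- ((dd + 180) %% 360) - 180
            expect_lte(abs(dd), 30 + 1e-9)
        }
    }

    # degenerate bound reproduces the template
    frozen <- generateCandidates(tmpl, rotamerSpec(nCandidates = 3L, libraryCap = 3L,
        dihedrals = aldimineDihedrals(maxPerturb = 0), seed = 1L))
    for (fr in frozen)
        expect_lt(max(abs(coords(fr) - coords(tmpl))), 1e-9)

    # seeded-RNG contract
    again <- generateCandidates(tmpl, spec)
    expect_identical(lapply(cand, coords), lapply(again, coords))
    other <- generateCandidates(tmpl, rotamerSpec(nCandidates = 10L,
                                                  libraryCap = 10L,
                                                  seed = 100L))
    expect_false(identical(lapply(cand, coords), lapply(other, coords)))
})

test_that("candidate generation demands the held chi1 value", {
    off <- buildFragment(3.0, 60, -100, 1.8)
    expect_error(generateCandidates(off, rotamerSpec(nCandidates = 2L, libraryCap = 2L)),
                 "not pre-set")
})

test_that("heavy-atom RMSD matches its analytic and brute-force oracles", {
    expect_identical(heavyAtomRmsd(tmpl, tmpl), 0)

    # one of four selected atoms displaced by 0.1 A: RMSD = 0.1 / sqrt(4)
    sel <- lapply(c("CA", "CB", "CG", "CD"), selALD)
    xyz <- coords(tmpl)
    xyz[which(atoms(tmpl)$name == "CD"), 1] <-
        xyz[which(atoms(tmpl)$name == "CD"), 1] + 0.1
    moved <- atomFrame(atoms(tmpl), xyz)
    expect_equal(heavyAtomRmsd(tmpl, moved, sel), 0.05, tolerance = 1e-12)

    withr::with_seed(41, {
        for (k in 1:20) {
            disp <- matrix(stats::rnorm(3 * nrow(atoms(tmpl)), 0, 0.3),
                           ncol = 3)
            b <- atomFrame(atoms(tmpl), coords(tmpl) + disp)
            heavy <- which(atoms(tmpl)$element != "H")
            oracle <- sqrt(sum(disp[heavy, ]^2) / length(heavy))
            expect_lt(abs(heavyAtomRmsd(tmpl, b) - oracle), 1e-12)
        }
    })

    other <- buildFragment(3, 60, -90, 1.8)
    other@atoms$name[1] <- "XX"
    expect_error(heavyAtomRmsd(tmpl, other), "selection mismatch")
})

test_that("clash score is zero at range, deterministic and monotone", {
    expect_identical(clashEnergy(twoAtomFrame(10)), 0)
    expect_identical(clashEnergy(tmpl), clashEnergy(tmpl))
    e3 <- clashEnergy(twoAtomFrame(3.0))
    e2 <- clashEnergy(twoAtomFrame(2.0))
    e1 <- clashEnergy(twoAtomFrame(1.0))
    expect_identical(e3, 0)
    expect_gt(e1, e2)
    expect_gt(e2, 0)
    # bonded pairs are excluded
    expect_identical(clashEnergy(twoAtomFrame(1.0),
                                 excludedPairs = rbind(c("X1", "X2"))), 0)
})

test_that("pruning enforces uniqueness, the distal-CA cutoff and the cap", {
    # bit-identical candidates collapse to a singleton
    lib1 <- pruneLibrary(rep(list(tmpl), 100), rotamerSpec(nCandidates = 100L, libraryCap = 50L),
                         tmpl)
    expect_identical(librarySize(lib1), 1L)

    # a candidate whose distal CA sits 3.0 A from the reference is dropped
    xyz <- coords(tmpl)
    cadIdx <- which(atoms(tmpl)$name == "CAD")
    xyz[cadIdx, ] <- xyz[cadIdx, ] + c(3, 0, 0)
    far <- atomFrame(atoms(tmpl), xyz)
    lib2 <- pruneLibrary(list(tmpl, far), rotamerSpec(nCandidates = 2L, libraryCap = 2L), tmpl)
    expect_identical(librarySize(lib2), 1L)
    expect_identical(coords(libraryRotamers(lib2)[[1]]), coords(tmpl))

    expect_error(pruneLibrary(list(), rotamerSpec(), tmpl), "empty")

    noCad <- roleMap(HZ = atomSelector("A", 46L, "HZ"),
                     CA = atomSelector("A", 500L, "CA"),
                     H99 = atomSelector("A", 500L, "H99"),
                     C50 = atomSelector("A", 500L, "C50"),
                     N99 = atomSelector("A", 500L, "N99"),
                     C80 = atomSelector("A", 500L, "C80"),
                     OE1 = atomSelector("A", 246L, "OE1"),
                     H1 = atomSelector("A", 500L, "H1"))
    expect_error(pruneLibrary(list(tmpl), rotamerSpec(), tmpl,
                              rolemap = noCad), "DISTAL_CA")
})

test_that("small-scale pruning satisfies the library invariants", {
    spec <- rotamerSpec(nCandidates = 300L, libraryCap = 60L, seed = 17L)
    cand <- generateCandidates(tmpl, spec)
    lib <- pruneLibrary(cand, spec, tmpl)
    expect_lte(librarySize(lib), 60L)
    rot <- libraryRotamers(lib)

    # brute-force pairwise RMSD floor over every retained pair
    for (i in seq_along(rot))
        for (j in seq_len(i - 1L))
            expect_gt(heavyAtomRmsd(rot[[i]], rot[[j]]),
                      spec@uniquenessRmsdMin)

    cadIdx <- which(atoms(tmpl)$name == "CAD")
    anchorIdx <- vapply(resolveRoles(tmpl, rmap)$PLP_ANCHOR_SET,
                        `[[`, integer(1), "index")
    for (fr in rot) {
        expect_lt(measureDistance(coords(fr)[cadIdx, ],
                                  coords(tmpl)[cadIdx, ]),
                  spec@distalCaMaxDev)
        expect_identical(coords(fr)[anchorIdx, ], coords(tmpl)[anchorIdx, ])
    }

    # deterministic given the spec and seed
    lib2 <- pruneLibrary(generateCandidates(tmpl, spec), spec, tmpl)
    expect_identical(lapply(libraryRotamers(lib2), coords),
                     lapply(rot, coords))

    # filter-only limit: no cap, vanishing uniqueness floor
    all_spec <- rotamerSpec(nCandidates = 300L, libraryCap = Inf,
                            uniquenessRmsdMin = 1e-12, seed = 17L)
    libAll <- pruneLibrary(cand, all_spec, tmpl)
    eligible <- sum(vapply(cand, function(fr)
        measureDistance(coords(fr)[cadIdx, ], coords(tmpl)[cadIdx, ]) <
            all_spec@distalCaMaxDev, logical(1)))
    expect_identical(librarySize(libAll), as.integer(eligible))
})
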