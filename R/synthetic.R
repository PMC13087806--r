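# Synthetic reagent collections with planted ground truth, and synthetic 3D
# poses for the pharmacophore checker. The generator emulates the kind of
# in-house reagent collection the enumeration was designed for: aryl
# carboxylic acids with aliphatic linkers, aromatic aldehydes, plus
# controlled fractions of salts, exact duplicates, stereocenter-bearing
# acids, fully aromatic (low-Fsp3) acids and non-acid decoys. All expected
# counts are fixed while the records are constructed - never measured
# afterwards - so they can serve as an independent reference for the
# pipeline.

# Component tables. Carbon and sp3-carbon counts are recorded alongside each
# fragment so that the Fsp3 of every future condensation product is known
# analytically at construction time (product sp3 carbons = acid sp3 carbons;
# product carbons = acid carbons + aldehyde carbons, the carbonyl carbon
# surviving as the imine CH).
.ARYL_POOL <- data.frame(
  smi = c("c1ccccc1", "c1ccncc1", "c1ccco1", "c1cccs1", "c1ccc2ccccc2c1",
          "c1ccncn1"),
  nc = c(6L, 5L, 4L, 4L, 10L, 4L),
  stringsAsFactors = FALSE)

.SUB_POOL <- data.frame(           # para-substituents, spliced into the aryl
  smi = c("", "F", "OC", "C"),
  nc = c(0L, 0L, 1L, 1L),
  sp3 = c(0L, 0L, 1L, 1L),
  stringsAsFactors = FALSE)

.ALD_ARYL_POOL <- data.frame(      # aldehyde aryls: aromatic, sp3-free
  smi = c("c1ccccc1", "c1ccncc1", "c1ccco1", "c1cccs1", "c1cncnc1",
          "c1ccc(F)cc1", "c1ccc(Cl)cc1", "c1cccnc1"),
  nc = c(6L, 5L, 4L, 4L, 4L, 6L, 6L, 5L),
  stringsAsFactors = FALSE)

# splice a para-substituent into a plain "c1ccXcc1"-type ring
.decorate <- function(aryl, sub) {
  if (sub == "") return(aryl)
  if (!grepl("^c1cc", aryl)) {
    stop("internal error: aryl template cannot take a substituent: ", aryl)
  }
  sub("^c1cc", paste0("c1cc(", sub, ")"), aryl)
}

#' Specification of a synthetic reagent library
#'
#' @param n_acids Number of acid records (including planted duplicates).
#' @param n_aldehydes Number of distinct aromatic aldehydes.
#' @param n_decoys Number of non-acid, non-aldehyde decoy records (esters,
#'   amides, plain aromatics).
#' @param salt_fraction Fraction of acid records spelled as sodium
#'   carboxylate salts (curation must strip and neutralize them).
#' @param duplicate_fraction Fraction of acid records that are exact
#'   duplicates of another record.
#' @param stereo_fraction Fraction of unique acids carrying one tetrahedral
#'   stereocenter (their products fail the stereocenter filter).
#' @param low_fsp3_fraction Fraction of unique acids that are fully aromatic
#'   (their products fail the Fsp3 filter).
#' @param seed Integer seed; the same spec and seed give a byte-identical
#'   library.
#' @return `nah_library_spec` object.
#' @export
reagent_library_spec <- function(n_acids = 20L, n_aldehydes = 5L,
                                 n_decoys = 0L, salt_fraction = 0,
                                 duplicate_fraction = 0, stereo_fraction = 0,
                                 low_fsp3_fraction = 0, seed = 1L) {
  fracs <- c(salt_fraction, duplicate_fraction, stereo_fraction,
             low_fsp3_fraction)
  stopifnot(all(fracs >= 0), all(fracs <= 1),
            n_acids >= 0, n_aldehydes >= 0, n_decoys >= 0)
  structure(list(n_acids = as.integer(n_acids),
                 n_aldehydes = as.integer(n_aldehydes),
                 n_decoys = as.integer(n_decoys),
                 salt_fraction = salt_fraction,
                 duplicate_fraction = duplicate_fraction,
                 stereo_fraction = stereo_fraction,
                 low_fsp3_fraction = low_fsp3_fraction,
                 seed = as.integer(seed)),
            class = "nah_library_spec")
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# enumerate the full template grid of one acid category and sample k rows
.sample_grid <- function(grid, k, what) {
  if (k > nrow(grid)) {
    stop(sprintf("infeasible spec: %d %s requested but only %d distinct ",
                 k, what, nrow(grid)), "templates exist", call. = FALSE)
  }
  grid[sample.int(nrow(grid), k), , drop = FALSE]
}

.acid_grids <- function() {
  clean <- expand.grid(m = 2:4, aryl = seq_len(nrow(.ARYL_POOL)),
                       sub = seq_len(nrow(.SUB_POOL)))
  lowf <- expand.grid(m = 0L, aryl = seq_len(nrow(.ARYL_POOL)),
                      sub = 1:2)  # H or F only: zero sp3 carbons
  stereo <- expand.grid(m = 1:2, aryl = seq_len(nrow(.ARYL_POOL)),
                        sub = seq_len(nrow(.SUB_POOL)))
  list(clean = clean, low_fsp3 = lowf, stereo = stereo)
}

.build_acid <- function(row, category) {
  aryl <- .ARYL_POOL[row$aryl, ]
  sub <- .SUB_POOL[row$sub, ]
  ar <- .decorate(aryl$smi, sub$smi)
  if (category == "stereo") {
    # alpha-methyl branch: one tetrahedral stereocenter at the alpha carbon
    smi <- paste0("OC(=O)C(C)", strrep("C", row$m), ar)
    sp3 <- 2L + row$m + sub$sp3
    nc <- 3L + row$m + aryl$nc + sub$nc
  } else {
    smi <- paste0("OC(=O)", strrep("C", row$m), ar)
    sp3 <- row$m + sub$sp3
    nc <- 1L + row$m + aryl$nc + sub$nc
  }
  list(smiles = smi, n_carbon = nc, n_sp3 = sp3, category = category)
}

.build_aldehyde <- function(idx) {
  a <- .ALD_ARYL_POOL[idx, ]
  list(smiles = paste0("O=C", a$smi), n_carbon = a$nc + 1L)
}

.build_decoys <- function(k) {
  grid <- expand.grid(head = c("COC(=O)C", "NC(=O)C", "CN(C)C(=O)C"),
                      aryl = seq_len(nrow(.ARYL_POOL)),
                      stringsAsFactors = FALSE)
  if (k > nrow(grid)) {
    stop("infeasible spec: too many decoys requested", call. = FALSE)
  }
  rows <- grid[sample.int(nrow(grid), k), , drop = FALSE]
  vapply(seq_len(nrow(rows)), function(i) {
    paste0(rows$head[i], .ARYL_POOL$smi[rows$aryl[i]])
  }, character(1))
}

.as_salt <- function(smiles) {
  paste0(sub("^OC\\(=O\\)", "[O-]C(=O)", smiles), ".[Na+]")
}

#' Generate a synthetic reagent library with planted ground truth
#'
#' Builds acid and aldehyde records by decorating aromatic scaffold
#' templates with linkers and substituents, then injects salts, exact
#' duplicates, stereocenter-bearing acids and fully aromatic (low-Fsp3)
#' acids at the requested fractions. Every acid template is constructed so
#' that the Fsp3 of each of its condensation products is known analytically,
#' which is how the expected filter counts are fixed during construction.
#'
#' @param spec A [reagent_library_spec()].
#' @return List with `records` (data.frame `id`, `smiles`, `role_hint`) and
#'   `ground_truth`: expected unique-acid / product / filter-pass counts and
#'   the per-record planted labels.
#' @examples
#' gl <- generate_library(reagent_library_spec(n_acids = 6, n_aldehydes = 3,
#'                                             seed = 7))
#' gl$ground_truth$expected_product_count
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "nah_library_spec"))
  k_dup <- round(spec$duplicate_fraction * spec$n_acids)
  n_unique <- spec$n_acids - k_dup
  if (n_unique < 1 && spec$n_acids > 0) {
    stop("infeasible spec: duplicate_fraction leaves no unique acid",
         call. = FALSE)
  }
  k_stereo <- round(spec$stereo_fraction * n_unique)
  k_low <- round(spec$low_fsp3_fraction * n_unique)
  k_clean <- n_unique - k_stereo - k_low
  if (k_clean < 0) {
    stop("infeasible spec: stereo_fraction + low_fsp3_fraction exceed 1",
         call. = FALSE)
  }
  .with_seed(spec$seed, {
    grids <- .acid_grids()
    pick <- function(grid, k, what, cat) {
      g <- .sample_grid(grid, k, what)
      g$category <- rep(cat, nrow(g))
      g
    }
    picked <- rbind(
      pick(grids$clean, k_clean, "clean acids", "clean"),
      pick(grids$low_fsp3, k_low, "low-Fsp3 acids", "low_fsp3"),
      pick(grids$stereo, k_stereo, "stereo acids", "stereo"))
    acid_defs <- lapply(seq_len(nrow(picked)), function(i) {
      .build_acid(picked[i, ], as.character(picked$category[i]))
    })
    # guaranteed by template design; a violation is a generator bug
    for (d in acid_defs) {
      lim <- d$n_sp3 / (d$n_carbon + max(.ALD_ARYL_POOL$nc) + 1L)
      if (d$category == "clean" && lim < 0.1) {
        stop("internal error: clean template below the Fsp3 floor")
      }
    }
    dup_src <- if (k_dup > 0) sample.int(n_unique, k_dup, replace = TRUE)
               else integer(0)
    all_smiles <- c(vapply(acid_defs, `[[`, character(1), "smiles"),
                    vapply(acid_defs[dup_src], `[[`, character(1), "smiles"))
    categories <- c(vapply(acid_defs, `[[`, character(1), "category"),
                    rep("duplicate", k_dup))
    shuffle <- sample.int(length(all_smiles))
    all_smiles <- all_smiles[shuffle]
    categories <- categories[shuffle]
    k_salt <- round(spec$salt_fraction * spec$n_acids)
    salted <- rep(FALSE, length(all_smiles))
    if (k_salt > 0) {
      idx <- sample.int(length(all_smiles), k_salt)
      all_smiles[idx] <- vapply(all_smiles[idx], .as_salt, character(1))
      salted[idx] <- TRUE
    }
    ald_idx <- .sample_grid(data.frame(i = seq_len(nrow(.ALD_ARYL_POOL))),
                            spec$n_aldehydes, "aldehydes")$i
    ald_smiles <- vapply(ald_idx, function(i) .build_aldehyde(i)$smiles,
                         character(1))
    decoys <- .build_decoys(spec$n_decoys)
    records <- data.frame(
      id = sprintf("SYN%04d",
                   seq_len(length(all_smiles) + length(ald_smiles) +
                             length(decoys))),
      smiles = c(all_smiles, ald_smiles, decoys),
      role_hint = c(rep("acid", length(all_smiles)),
                    rep("aldehyde", length(ald_smiles)),
                    rep("decoy", length(decoys))),
      stringsAsFactors = FALSE)
    ground_truth <- list(
      expected_acid_count = n_unique,
      expected_aldehyde_count = spec$n_aldehydes,
      expected_product_count = n_unique * spec$n_aldehydes,
      expected_pass_filter_count = k_clean * spec$n_aldehydes,
      expected_stereo_fail_count = k_stereo * spec$n_aldehydes,
      expected_low_fsp3_fail_count = k_low * spec$n_aldehydes,
      labels = data.frame(id = records$id,
                          category = c(categories,
                                       rep("aldehyde", length(ald_smiles)),
                                       rep("decoy", length(decoys))),
                          salt = c(salted, rep(FALSE, length(ald_smiles) +
                                                 length(decoys))),
                          stringsAsFactors = FALSE))
    list(records = records, ground_truth = ground_truth)
  })
}

#' Generate labeled synthetic poses for the pharmacophore checker
#'
#' Builds minimal molecules with one donor (primary amine nitrogen) per
#' donor point and one acceptor (ether oxygen) per acceptor point, then
#' places the feature atoms inside their constraint spheres for poses
#' labeled satisfied, and at least 8 Angstrom away from every sphere for the
#' feature chosen to fail otherwise. Placement is deterministic given the
#' labels and seed, so checker agreement with the labels is exact by
#' construction.
#'
#' @param n Number of poses.
#' @param points Constraint points (default [default_pharmacophore()]).
#' @param satisfied_fraction Target fraction of satisfied poses.
#' @param seed Integer seed.
#' @return List with `poses` (list of `nah_pose`) and `labels` (logical).
#' @export
generate_poses <- function(n, points = default_pharmacophore(),
                           satisfied_fraction = 0.5, seed = 1L) {
  stopifnot(n >= 0, satisfied_fraction >= 0, satisfied_fraction <= 1)
  feats <- vapply(points, function(p) p$feature, character(1))
  d <- sum(feats == "HBD")
  a <- sum(feats == "HBA")
  smi <- paste0(strrep("C(N)", max(d, 1)), strrep("C(OC)", max(a, 1)))
  mol <- mol_parse(smi)
  fa <- .feature_atoms(mol)
  centers <- do.call(rbind, lapply(points, function(p) p$center))
  mid <- colMeans(centers)
  .with_seed(seed, {
    k <- round(satisfied_fraction * n)
    labels <- sample(c(rep(TRUE, k), rep(FALSE, n - k)))
    unit <- function() {
      v <- rnorm(3)
      v / sqrt(sum(v^2))
    }
    poses <- lapply(seq_len(n), function(i) {
      coords <- matrix(0, nrow(mol$atoms), 3)
      # park every atom well outside all spheres first
      for (j in seq_len(nrow(coords))) {
        coords[j, ] <- mid + unit() * (12 + runif(1, 0, 6))
      }
      sat <- labels[i]
      fail_at <- if (!sat) sample.int(length(points), 1) else 0L
      for (pi in seq_along(points)) {
        p <- points[[pi]]
        pool <- fa[[p$feature]]
        atom <- pool[min(pi, length(pool))]
        if (sat || pi != fail_at) {
          coords[atom, ] <- p$center + unit() * runif(1, 0, 0.85 * p$radius)
        }
        # else: the atom stays parked far away and the point fails
      }
      pose(mol, coords)
    })
    list(poses = poses, labels = labels)
  })
}
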