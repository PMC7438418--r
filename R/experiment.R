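#' Design for a training-data-diversity experiment
#'
#' Describes equal-size training cohorts that differ only in their
#' pathology mix, a shared (pathologically diverse) test set, the model
#' variants to cross with the cohorts, and replicate seeds. Training and
#' test cases draw from disjoint seed streams by construction, which the
#' runner additionally asserts.
#'
#' @param cohorts named list of [phantom_spec()]s, one per training cohort;
#'   all cohorts use the same `n`.
#' @param test_spec [phantom_spec()] for the shared test set (typically a
#'   full pathology mix).
#' @param n cases per training cohort.
#' @param n_test cases in the shared test set.
#' @param variants character, model variants to cross (`"unet"`,
#'   `"resunet"`).
#' @param seeds integer vector of replicate seeds.
#' @param net base network profile as a [net_config()] (the variant field
#'   is overridden per run).
#' @param target_size slice size for training and inference.
#' @param train a [train_config()] template (its seed is overridden per
#'   run).
#' @return An object of class `diversity_design`.
#' @export
diversity_design <- function(cohorts, test_spec, n = 16L, n_test = 12L,
                             variants = "unet", seeds = 1:3,
                             net = net_config(base_width = 8L, depth = 4L),
                             target_size = c(64L, 64L),
                             train = train_config(epochs = 20L, lr = 0.1,
                                                  val_fraction = 0.15)) {
  assert_that(is.list(cohorts) && length(cohorts) >= 2 && !is.null(names(cohorts)),
              "cohorts must be a named list of at least two phantom_specs")
  for (sp in cohorts) assert_that(inherits(sp, "phantom_spec"),
                                  "every cohort must be a phantom_spec")
  assert_that(inherits(test_spec, "phantom_spec"), "test_spec must be a phantom_spec")
  structure(
    list(cohorts = cohorts, test_spec = test_spec, n = as.integer(n),
         n_test = as.integer(n_test), variants = variants,
         seeds = as.integer(seeds), net = net,
         target_size = as.integer(target_size), train = train),
    class = "diversity_design"
  )
}

#' Run the diversity experiment
#'
#' For each cohort x variant x seed cell: generate the training cohort,
#' train from scratch, segment the shared test set, and evaluate DSC, HD95
#' and MSD per case (per-lung averaged). Training divergence in a cell is
#' caught, flagged, and the experiment continues. Results come back as a
#' per-case table, a summary grid of mean ± SD per cell, and paired
#' t-tests between cohorts on per-case DSC (same variant and seed, paired
#' by test case).
#'
#' @param design a [diversity_design()].
#' @param quiet suppress progress messages.
#' @return An object of class `diversity_result`: list with `per_case`,
#'   `grid`, `tests`, and `design`.
#' @export
run_diversity_experiment <- function(design, quiet = TRUE) {
  assert_that(inherits(design, "diversity_design"), "design must be a diversity_design")
  # test seeds come from a stream offset far from any training seed
  test_seed <- max(design$seeds) * 1000L + 999L
  test_cases <- generate_cohort(design$test_spec, design$n_test, seed = test_seed)
  test_gts <- lapply(test_cases, `[[`, "lung_mask")
  train_seed_of <- function(seed, cohort_idx) seed * 1000L + cohort_idx
  train_seeds <- outer(design$seeds, seq_along(design$cohorts), train_seed_of)
  assert_that(length(intersect(as.vector(train_seeds), test_seed)) == 0,
              "training and test seeds must be disjoint")

  per_case <- list()
  for (variant in design$variants) {
    for (ci in seq_along(design$cohorts)) {
      cohort_name <- names(design$cohorts)[ci]
      for (seed in design$seeds) {
        run_seed <- train_seed_of(seed, ci)
        cell <- sprintf("%s/%s/seed%d", variant, cohort_name, seed)
        if (!quiet) message("cell ", cell)
        res <- tryCatch({
          train_cases <- generate_cohort(design$cohorts[[ci]], design$n, seed = run_seed)
          records <- slice_records(train_cases, target_size = design$target_size)
          cfg <- design$net
          cfg$variant <- variant
          tc <- design$train
          tc$seed <- run_seed
          model <- withr::with_seed(run_seed, build_model(cfg))
          model <- train_model(model, records, tc)
          rows <- purrr::map2(test_cases, test_gts, function(cs, gt) {
            pred <- segment_volume(model, cs$volume, target_size = design$target_size)
            ev <- evaluate_case(pred, gt)
            ev$pathology <- cs$pathology
            ev
          })
          dplyr::bind_rows(rows)
        }, thoraxseg_divergence = function(e) NULL,
           error = function(e) {
             if (grepl("diverged", conditionMessage(e))) NULL else stop(e)
           })
        if (is.null(res)) {
          per_case[[cell]] <- tibble(case = NA_character_, label = NA_character_,
                                     dsc = NA_real_, hd95_mm = NA_real_,
                                     msd_mm = NA_real_, pathology = NA_character_,
                                     variant = variant, cohort = cohort_name,
                                     seed = seed, diverged = TRUE)
        } else {
          res$variant <- variant
          res$cohort <- cohort_name
          res$seed <- seed
          res$diverged <- FALSE
          per_case[[cell]] <- res
        }
      }
    }
  }
  per_case <- dplyr::bind_rows(per_case)
  means <- per_case |>
    dplyr::filter(.data$label == "mean", !.data$diverged)
  grid <- means |>
    dplyr::group_by(.data$variant, .data$cohort, .data$seed) |>
    dplyr::summarise(
      n_cases = dplyr::n(),
      dsc_mean = mean(.data$dsc), dsc_sd = sd(.data$dsc),
      hd95_mean = mean(.data$hd95_mm, na.rm = TRUE),
      hd95_sd = sd(.data$hd95_mm, na.rm = TRUE),
      msd_mean = mean(.data$msd_mm, na.rm = TRUE),
      msd_sd = sd(.data$msd_mm, na.rm = TRUE),
      .groups = "drop"
    )
  tests <- list()
  cohort_names <- names(design$cohorts)
  if (length(cohort_names) >= 2) {
    pairs <- utils::combn(cohort_names, 2, simplify = FALSE)
    for (variant in design$variants) for (seed in design$seeds) for (pr in pairs) {
      a <- means |> dplyr::filter(.data$variant == !!variant, .data$seed == !!seed,
                                  .data$cohort == pr[1]) |> dplyr::arrange(.data$case)
      b <- means |> dplyr::filter(.data$variant == !!variant, .data$seed == !!seed,
                                  .data$cohort == pr[2]) |> dplyr::arrange(.data$case)
      if (nrow(a) >= 2 && nrow(a) == nrow(b) && sd(a$dsc - b$dsc) > 0) {
        tt <- paired_t(a$dsc, b$dsc)
        tt$variant <- variant; tt$seed <- seed
        tt$cohort_a <- pr[1]; tt$cohort_b <- pr[2]
        tests[[length(tests) + 1]] <- tt
      }
    }
  }
  structure(
    list(per_case = per_case, grid = grid,
         tests = dplyr::bind_rows(tests), design = design),
    class = "diversity_result"
  )
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("<diversity_result>\n")
  print(as.data.frame(x$grid), digits = 3)
  if (nrow(x$tests) > 0) {
    cat("paired t-tests (per-case DSC):\n")
    print(as.data.frame(x$tests), digits = 3)
  }
  invisible(x)
}

#' @export
tidy.diversity_result <- function(x, ...) x$grid

#' @export
glance.diversity_result <- function(x, ...) {
  x$grid |>
    dplyr::group_by(.data$variant, .data$cohort) |>
    dplyr::summarise(dsc_mean = mean(.data$dsc_mean),
                     hd95_mean = mean(.data$hd95_mean),
                     msd_mean = mean(.data$msd_mean),
                     n_seeds = dplyr::n(), .groups = "drop")
}

#' Plot a diversity experiment result
#'
#' Per-case averaged DSC by training cohort, faceted by model variant;
#' one point per test case, coloured by replicate seed.
#'
#' @param object a `diversity_result`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.diversity_result <- function(object, ...) {
  df <- object$per_case |> dplyr::filter(.data$label == "mean", !.data$diverged)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cohort, y = .data$dsc,
                                   colour = factor(.data$seed))) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "black", linewidth = 0.3) +
    ggplot2::facet_wrap(~variant) +
    ggplot2::labs(x = "training cohort", y = "per-case averaged DSC",
                  colour = "seed") +
    ggplot2::theme_minimal()
}
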