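# Synthetic severity-image generator.
#
# Emulates the study design in which a continuous latent severity s in [0,1]
# drives a visible image feature, training labels are obtained by threshold
# discretization of s into K ordinal classes, and the evaluation set carries
# finer-grained references than the training labels: expert rank lists,
# 9-point median ratings from several noisy raters, and a noisy continuous
# measurement standing in for an independent software-derived reference.

#' Define an ordinal labelling scheme
#'
#' An ordinal scheme discretizes the latent severity `s` in \[0,1\] into `K`
#' ordered classes using `K - 1` strictly increasing thresholds. A severity
#' exactly on a threshold belongs to the upper class (half-open bins,
#' `class = #\{t : s >= t\}`).
#'
#' @param K integer number of classes (>= 2).
#' @param thresholds strictly increasing numeric vector of length `K - 1`
#'   inside (0, 1). Default: equal-width bins `seq_len(K - 1) / K`.
#' @param class_names character vector of `K` class names.
#' @return an object of class `ordinal_scheme`.
#' @examples
#' sch <- ordinal_scheme(3)
#' discretize_severity(c(0.1, 0.5, 2/3), sch)  # 0 1 2
#' @export
ordinal_scheme <- function(K = 3L,
                           thresholds = seq_len(K - 1) / K,
                           class_names = paste0("class", 0:(K - 1))) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (length(thresholds) != K - 1L)
    stop("need K - 1 thresholds", call. = FALSE)
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)", call. = FALSE)
  if (length(class_names) != K)
    stop("need K class names", call. = FALSE)
  structure(list(K = K, thresholds = as.numeric(thresholds),
                 class_names = as.character(class_names)),
            class = "ordinal_scheme")
}

#' Discretize a latent severity into an ordinal class
#'
#' Uses half-open bins: the returned class is the number of thresholds less
#' than or equal to `s`, so a severity exactly on a threshold falls in the
#' upper class. Classes are 0-based (`0 .. K-1`).
#'
#' @param s numeric vector of severities in \[0,1\].
#' @param scheme an [ordinal_scheme()].
#' @return integer vector of class indices in `0 .. K-1`.
#' @export
discretize_severity <- function(s, scheme) {
  check_severity(s)
  stopifnot(inherits(scheme, "ordinal_scheme"))
  findInterval(s, scheme$thresholds)
}

check_severity <- function(s) {
  if (!is.numeric(s) || anyNA(s) || any(s < 0 | s > 1))
    stop("severity `s` must lie in [0, 1]", call. = FALSE)
  invisible(s)
}

#' Render a synthetic severity image
#'
#' Produces a `side x side` grayscale image in \[0,1\] containing a central
#' bright "lesion" disc whose radius and intensity both increase with the
#' latent severity `s`, a vessel-like tortuous curve whose tortuosity grows
#' with `s`, and a smooth per-subject background texture fixed by
#' `subject_seed`. Gaussian pixel noise with standard deviation `noise_sd` is
#' added last and the result clipped to \[0,1\]. The render is fully
#' deterministic given `(s, subject_seed, noise_sd)`; two timepoints of the
#' same subject share the background and differ only through `s` and noise.
#'
#' Geometry: the disc has radius `r(s) = min_radius + s * (max_radius -
#' min_radius)` pixels and uniform intensity `0.55 + 0.35 * s`; background
#' amplitude stays below 0.3 and the vessel below 0.45, so pixels above 0.5
#' are exactly the disc.
#'
#' @param s latent severity in \[0,1\].
#' @param subject_seed integer; fixes background texture and vessel phase.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param side image side length in pixels.
#' @param min_radius,max_radius lesion disc radius (pixels) at `s = 0` and
#'   `s = 1`.
#' @return numeric `side x side` matrix with values in \[0,1\].
#' @export
render_image <- function(s, subject_seed = 0L, noise_sd = 0.05, side = 64L,
                         min_radius = 3, max_radius = 0.3 * side) {
  check_severity(s)
  stopifnot(length(s) == 1L, noise_sd >= 0, side >= 16L)

  cx <- (side + 1) / 2
  xs <- seq_len(side)
  dist <- sqrt(outer((xs - cx)^2, (xs - cx)^2, `+`))

  # per-subject background: low-frequency cosine mixture in [0, 0.3],
  # plus the vessel phase, all drawn from subject_seed only
  bgpar <- with_seed(mix_seed(subject_seed, 1299709), {
    list(a = runif(3, -1, 1), fx = runif(3, 0.5, 2), fy = runif(3, 0.5, 2),
         ph = runif(3, 0, 2 * pi), vessel_phase = runif(1, 0, 2 * pi))
  })
  u <- xs / side
  bg <- matrix(0, side, side)
  for (j in 1:3) {
    bg <- bg + bgpar$a[j] *
      outer(cos(2 * pi * bgpar$fx[j] * u + bgpar$ph[j]),
            cos(2 * pi * bgpar$fy[j] * u))
  }
  bg <- 0.15 + 0.15 * bg / 3          # in [0, 0.3]
  img <- bg

  # vessel: tortuous curve from the centre outwards; amplitude of the
  # oscillation grows with s (tortuosity), intensity capped at 0.4
  tpts <- seq(0, 1, length.out = 8L * side)
  rad <- tpts * (side / 2 - 2)
  ang <- bgpar$vessel_phase + 2 * pi * tpts +
    (0.5 + 2.5 * s) * sin(6 * pi * tpts)
  vx <- round(cx + rad * cos(ang))
  vy <- round(cx + rad * sin(ang))
  ok <- vx >= 1 & vx <= side & vy >= 1 & vy <= side
  img[cbind(vy[ok], vx[ok])] <- 0.4

  # lesion disc: radius and intensity strictly increasing in s
  r <- min_radius + s * (max_radius - min_radius)
  disc <- dist <= r
  img[disc] <- 0.55 + 0.35 * s

  if (noise_sd > 0) {
    noise_seed <- mix_seed(subject_seed, round(s * 2^20),
                           round(noise_sd * 1e6))
    img <- img + with_seed(noise_seed, matrix(rnorm(side^2, 0, noise_sd),
                                              side, side))
  }
  clamp(img, 0, 1)
}

#' Lesion extent statistics of a rendered image
#'
#' `lesion_pixel_count()` counts pixels brighter than `threshold`;
#' at `noise_sd = 0` these are exactly the lesion disc pixels.
#' `lesion_extent()` sums the intensity excess above the threshold, a
#' continuous statistic that is strictly increasing in the latent severity
#' for noiseless renders.
#'
#' @param image numeric matrix from [render_image()].
#' @param threshold intensity cut separating lesion from background.
#' @return a count (integer) or an intensity mass (numeric).
#' @export
lesion_pixel_count <- function(image, threshold = 0.5) {
  sum(image > threshold)
}

#' @rdname lesion_pixel_count
#' @export
lesion_extent <- function(image, threshold = 0.5) {
  sum(pmax(image - threshold, 0))
}

#' Simulate a median 9-point expert rating
#'
#' Each of `n_raters` raters rates the image as
#' `clip(round(1 + 8 * (s + e)), 1, 9)` with rater noise
#' `e ~ Normal(0, rater_sd)`; the returned rating is the median across
#' raters (an integer for the default odd rater count).
#'
#' @param s latent severity in \[0,1\] (vectorized).
#' @param n_raters number of simulated raters (default 5).
#' @param rater_sd standard deviation of per-rater noise on the `s` scale.
#' @param seed integer seed.
#' @return integer vector of ratings in 1..9.
#' @export
simulate_fine_ratings <- function(s, n_raters = 5L, rater_sd = 0.1,
                                  seed = 1L) {
  check_severity(s)
  stopifnot(n_raters >= 1L, rater_sd >= 0)
  with_seed(seed, {
    vapply(s, function(si) {
      e <- rnorm(n_raters, 0, rater_sd)
      r <- clamp(round(1 + 8 * (si + e)), 1, 9)
      as.integer(round(median(r)))
    }, integer(1))
  })
}

#' Generate a synthetic ordinal-severity image dataset
#'
#' Draws `n` subjects with latent severity `s ~ Uniform(0,1)`, discretizes
#' `s` into ordinal training labels, splits subjects (not images) into
#' train/validation/test, and equips the test split with the finer-grained
#' evaluation references: a total severity rank list (ascending in `s`, ties
#' broken by subject id), simulated 9-point median ratings, and a noisy
#' continuous reference `s + Normal(0, ref_sd)`. A fraction of subjects in
#' every split receives a second longitudinal timepoint with
#' `s2 = clip(s1 + Uniform(-0.3, 0.3), 0, 1)` rendered on the same
#' subject-specific background.
#'
#' @param n number of subjects (>= 10).
#' @param scheme an [ordinal_scheme()].
#' @param split_fractions named numeric vector `(train, val, test)` summing
#'   to 1.
#' @param seed master seed; everything downstream is deterministic in it.
#' @param longitudinal_fraction fraction of subjects with a second timepoint.
#' @param noise_sd,side,min_radius,max_radius passed to [render_image()].
#' @param n_raters,rater_sd passed to [simulate_fine_ratings()].
#' @param ref_sd standard deviation of the continuous reference noise.
#' @param render if `FALSE`, only the manifest is produced (no images);
#'   useful for label-distribution studies at large `n`.
#' @return an object of class `sev_dataset`: a list with `manifest` (a
#'   data.frame with columns path, subject_id, timepoint, split, label, s,
#'   rating_1to9, rank, continuous_ref), `images` (array
#'   `side x side x nrow(manifest)` or `NULL`), and `params`.
#' @export
generate_dataset <- function(n, scheme = ordinal_scheme(3),
                             split_fractions = c(train = 0.7, val = 0.15,
                                                 test = 0.15),
                             seed = 1L, longitudinal_fraction = 0.3,
                             noise_sd = 0.05, side = 64L,
                             min_radius = 3, max_radius = 0.3 * side,
                             n_raters = 5L, rater_sd = 0.1, ref_sd = 0.05,
                             render = TRUE) {
  stopifnot(n >= 10L, inherits(scheme, "ordinal_scheme"))
  if (length(split_fractions) != 3L ||
      abs(sum(split_fractions) - 1) > 1e-8 || any(split_fractions < 0))
    stop("split_fractions must be 3 nonnegative numbers summing to 1",
         call. = FALSE)
  if (is.null(names(split_fractions)))
    names(split_fractions) <- c("train", "val", "test")
  stopifnot(longitudinal_fraction >= 0, longitudinal_fraction <= 1)

  man <- with_seed(mix_seed(seed, 17L), {
    subject_id <- sprintf("subj%05d", seq_len(n))
    s1 <- runif(n)

    # subject-level split with largest-remainder rounding
    counts <- floor(split_fractions * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(split_fractions * n - counts, decreasing = TRUE)
      counts[extra[seq_len(rem)]] <- counts[extra[seq_len(rem)]] + 1L
    }
    split <- rep(names(split_fractions), counts)[sample.int(n)]

    long <- runif(n) < longitudinal_fraction
    s2 <- clamp(s1 + runif(n, -0.3, 0.3), 0, 1)

    base <- data.frame(subject_id = subject_id, timepoint = 0L,
                       split = split, s = s1, stringsAsFactors = FALSE)
    fup <- data.frame(subject_id = subject_id[long],
                      timepoint = rep(1L, sum(long)),
                      split = split[long], s = s2[long],
                      stringsAsFactors = FALSE)
    man <- rbind(base, fup)
    man$label <- discretize_severity(man$s, scheme)
    man$subject_seed <- as.integer((mix_seed(seed, 7919L) +
      match(man$subject_id, subject_id)) %% 2147483647)

    # fine-grained references on the test split only
    man$rating_1to9 <- NA_integer_
    man$rank <- NA_integer_
    man$continuous_ref <- NA_real_
    te <- which(man$split == "test")
    if (length(te)) {
      man$rating_1to9[te] <- simulate_fine_ratings(
        man$s[te], n_raters, rater_sd, seed = mix_seed(seed, 23L))
      man$continuous_ref[te] <- man$s[te] + rnorm(length(te), 0, ref_sd)
    }
    # total-order rank list over baseline test images, ascending in s
    rk <- which(man$split == "test" & man$timepoint == 0L)
    if (length(rk)) {
      o <- rk[order(man$s[rk], man$subject_id[rk])]
      man$rank[o] <- seq_along(o)
    }
    man$path <- sprintf("%s_t%d.png", man$subject_id, man$timepoint)
    man[order(man$subject_id, man$timepoint),
        c("path", "subject_id", "timepoint", "split", "label", "s",
          "rating_1to9", "rank", "continuous_ref", "subject_seed")]
  })
  rownames(man) <- NULL

  images <- NULL
  if (render) {
    images <- array(0, dim = c(side, side, nrow(man)))
    for (i in seq_len(nrow(man))) {
      images[, , i] <- render_image(man$s[i], man$subject_seed[i],
                                    noise_sd = noise_sd, side = side,
                                    min_radius = min_radius,
                                    max_radius = max_radius)
    }
  }

  structure(list(
    manifest = man, images = images,
    params = list(n = n, K = scheme$K, thresholds = scheme$thresholds,
                  class_names = scheme$class_names,
                  split_fractions = as.list(split_fractions), seed = seed,
                  longitudinal_fraction = longitudinal_fraction,
                  noise_sd = noise_sd, side = side,
                  min_radius = min_radius, max_radius = max_radius,
                  n_raters = n_raters, rater_sd = rater_sd,
                  ref_sd = ref_sd)),
    class = "sev_dataset")
}

#' @export
print.sev_dataset <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<sev_dataset> %d images, %d subjects, K = %d, side = %d\n",
              nrow(m), length(unique(m$subject_id)), x$params$K,
              x$params$side))
  print(table(split = m$split, timepoint = m$timepoint))
  invisible(x)
}

#' Subset a dataset by split
#'
#' @param dataset a `sev_dataset`.
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @param timepoint optional timepoint filter.
#' @return a list with `manifest` and `images` restricted to the split.
#' @export
dataset_split <- function(dataset, split, timepoint = NULL) {
  stopifnot(inherits(dataset, "sev_dataset"))
  keep <- dataset$manifest$split == split
  if (!is.null(timepoint)) keep <- keep & dataset$manifest$timepoint %in% timepoint
  list(manifest = dataset$manifest[keep, , drop = FALSE],
       images = if (!is.null(dataset$images))
         dataset$images[, , keep, drop = FALSE])
}

#' Write a dataset to disk (PNG images + CSV manifest + JSON sidecar)
#'
#' @param dataset a rendered `sev_dataset`.
#' @param dir output directory.
#' @param force overwrite a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, force = FALSE) {
  stopifnot(inherits(dataset, "sev_dataset"))
  if (is.null(dataset$images))
    stop("dataset was generated with render = FALSE", call. = FALSE)
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force)
    stop("output directory is not empty (use force = TRUE)", call. = FALSE)
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  man <- dataset$manifest
  for (i in seq_len(nrow(man))) {
    png::writePNG(dataset$images[, , i],
                  file.path(dir, "images", man$path[i]))
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(dataset$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a `sev_dataset` (images re-quantized to 8 bit by the PNG round
#'   trip).
#' @export
read_dataset <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"),
                  stringsAsFactors = FALSE)
  params <- jsonlite::read_json(file.path(dir, "params.json"),
                                simplifyVector = TRUE)
  side <- params$side
  images <- array(0, dim = c(side, side, nrow(man)))
  for (i in seq_len(nrow(man))) {
    img <- png::readPNG(file.path(dir, "images", man$path[i]))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    images[, , i] <- img
  }
  structure(list(manifest = man, images = images, params = params),
            class = "sev_dataset")
}
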