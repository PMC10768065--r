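# Procedural synthetic crop/weed scenes: a textured soil or paddy
# background, a few large rosette-shaped crops, many small thin-bladed
# weeds, with exactly aligned image and label rasters. Scenes emulate the
# structure of robot/UAV field datasets (few large crops, many small
# dispersed weeds) without reproducing any real imagery.

#' Synthetic scene specification
#'
#' @param size canvas `c(H, W)` in pixels.
#' @param n_crops number of large rosette-shaped crop plants.
#' @param n_weeds number of small thin-bladed weeds.
#' @param crop_radius_range crop rosette radius range in pixels.
#' @param weed_radius_range weed radius range in pixels; must be strictly
#'   smaller than the crop radii (weeds are "small and dispersed").
#' @param overlap_prob probability that a weed is allowed to grow on top of
#'   a crop rosette; 0 keeps all plants disjoint.
#' @param background `"soil"` (brown, robot-view) or `"paddy"`
#'   (green-blue water, UAV-view).
#' @param reflection paddy only: paint blurred plant "reflections" that
#'   stay labelled as background.
#' @param noise_level standard deviation of the additive pixel noise.
#' @param seed integer seed; identical specs give identical scenes.
#' @return a `ws_scene_spec` list.
#' @export
scene_spec <- function(size = c(256, 256), n_crops = 3, n_weeds = 12,
                       crop_radius_range = c(24, 40),
                       weed_radius_range = c(4, 9),
                       overlap_prob = 0.1, background = c("soil", "paddy"),
                       reflection = FALSE, noise_level = 0.04, seed = 1L) {
  background <- match.arg(background)
  if (max(weed_radius_range) >= min(crop_radius_range))
    stop("scene_spec: weed radii must be strictly smaller than crop radii")
  if (overlap_prob < 0 || overlap_prob > 1)
    stop("scene_spec: `overlap_prob` must lie in [0, 1]")
  if (any(size < 16)) stop("scene_spec: canvas must be at least 16 x 16")
  structure(list(size = as.integer(size), n_crops = as.integer(n_crops),
                 n_weeds = as.integer(n_weeds),
                 crop_radius_range = crop_radius_range,
                 weed_radius_range = weed_radius_range,
                 overlap_prob = overlap_prob, background = background,
                 reflection = isTRUE(reflection),
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "ws_scene_spec")
}

# low-frequency value noise: coarse grid upsampled bilinearly
.value_noise <- function(H, W, cells = 8, amp = 1) {
  g <- matrix(runif(cells * cells, -1, 1), cells, cells)
  resize_bilinear(g, c(H, W)) * amp
}

.rosette <- function(H, W, cy, cx, radius) {
  # radial petals around the centre; returns a logical membership mask
  n_pet <- sample(7:11, 1)
  th0 <- runif(1, 0, 2 * pi)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  mem <- matrix(FALSE, H, W)
  for (p in seq_len(n_pet)) {
    th <- th0 + 2 * pi * p / n_pet + runif(1, -0.1, 0.1)
    a <- radius * runif(1, 0.85, 1)     # petal length
    b <- radius * runif(1, 0.22, 0.32)  # petal half width
    # petal centred half way along its axis
    pcy <- cy + 0.5 * a * sin(th)
    pcx <- cx + 0.5 * a * cos(th)
    u <- (rows - pcy) * sin(th) + (cols - pcx) * cos(th)
    v <- -(rows - pcy) * cos(th) + (cols - pcx) * sin(th)
    mem <- mem | ((u / (0.55 * a))^2 + (v / b)^2 <= 1)
  }
  # a small core disc so petals always connect
  mem | ((rows - cy)^2 + (cols - cx)^2 <= (0.3 * radius)^2)
}

.blade <- function(H, W, cy, cx, radius) {
  # a weed: 2-4 thin strokes radiating from a base point
  n_str <- sample(2:4, 1)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  mem <- matrix(FALSE, H, W)
  for (s in seq_len(n_str)) {
    th <- runif(1, 0, 2 * pi)
    len <- radius * runif(1, 1.2, 2)
    wid <- runif(1, 0.6, 1.1)
    ey <- cy + len * sin(th)
    ex <- cx + len * cos(th)
    # distance from each pixel to the segment (cy,cx)-(ey,ex)
    dy <- ey - cy; dx <- ex - cx
    l2 <- dy^2 + dx^2
    t <- pmin(pmax(((rows - cy) * dy + (cols - cx) * dx) / l2, 0), 1)
    d2 <- (rows - (cy + t * dy))^2 + (cols - (cx + t * dx))^2
    mem <- mem | (d2 <= wid^2)
  }
  mem
}

.paint <- function(img, mem, col, shade) {
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[mem] <- pmin(pmax(col[ch] * shade[mem], 0), 1)
    img[, , ch] <- pl
  }
  img
}

#' Generate one synthetic crop/weed scene
#'
#' Renders the background texture, `n_crops` large green rosettes (label 1)
#' and `n_weeds` small thin lighter-green blades (label 2) onto an aligned
#' image/mask pair. With `overlap_prob = 0` all plants are kept disjoint,
#' so the mask has exactly `n_crops` connected crop components.
#'
#' @param spec a [scene_spec()].
#' @return `list(image =, mask =)`: an `H x W x 3` array in `[0, 1]` and an
#'   integer `H x W` mask over `{0, 1, 2}`.
#' @examples
#' sc <- generate_synthetic_scene(scene_spec(size = c(64, 64), seed = 7))
#' table(sc$mask)
#' @export
generate_synthetic_scene <- function(spec) {
  stopifnot(inherits(spec, "ws_scene_spec"))
  H <- spec$size[1]; W <- spec$size[2]
  rmax <- max(spec$crop_radius_range)
  if (2 * rmax + 4 > min(H, W))
    stop("generate_synthetic_scene: crop radius ", rmax,
         " does not fit the ", H, "x", W, " canvas")
  with_seed(spec$seed, {
    img <- array(0, c(H, W, 3))
    base <- if (spec$background == "soil") c(0.34, 0.25, 0.17)
            else c(0.22, 0.33, 0.36)
    lf <- .value_noise(H, W, cells = 8, amp = 0.06)
    for (ch in 1:3) img[, , ch] <- base[ch] + lf * (0.6 + 0.4 * ch / 3)
    if (spec$background == "paddy") {
      # horizontal ripple bands
      ripple <- 0.02 * sin(outer(seq_len(H) / 6, rep(1, W)) +
                             .value_noise(H, W, 6, 2))
      for (ch in 2:3) img[, , ch] <- img[, , ch] + ripple
    }
    mask <- matrix(0L, H, W)
    shade <- 1 + .value_noise(H, W, 10, 0.12)

    # crops: rejection-sampled so rosettes never touch each other
    centres <- matrix(numeric(0), 0, 3)
    for (i in seq_len(spec$n_crops)) {
      r <- runif(1, spec$crop_radius_range[1], spec$crop_radius_range[2])
      ok <- FALSE
      for (try in 1:200) {
        cy <- runif(1, r + 2, H - r - 1)
        cx <- runif(1, r + 2, W - r - 1)
        if (nrow(centres) == 0 ||
            all(sqrt((centres[, 1] - cy)^2 + (centres[, 2] - cx)^2) >
                centres[, 3] + r + 4)) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("generate_synthetic_scene: cannot place ", spec$n_crops,
             " non-overlapping crops of this size on the canvas")
      centres <- rbind(centres, c(cy, cx, r))
      mem <- .rosette(H, W, cy, cx, r)
      if (spec$reflection && spec$background == "paddy") {
        refl <- gaussian_blur(0.35 * (mem * 1), 2.5)
        img[, , 2] <- img[, , 2] + refl * 0.25 # greenish sheen, label stays 0
      }
      img <- .paint(img, mem, c(0.10, 0.42, 0.12), shade)
      mask[mem] <- 1L
    }

    # weeds: lighter, yellow-green, thin
    for (i in seq_len(spec$n_weeds)) {
      r <- runif(1, spec$weed_radius_range[1], spec$weed_radius_range[2])
      allow_overlap <- runif(1) < spec$overlap_prob
      placed <- FALSE
      for (try in 1:200) {
        m <- 2.2 * r + 2
        cy <- runif(1, m, H - m)
        cx <- runif(1, m, W - m)
        if (allow_overlap || nrow(centres) == 0 ||
            all(sqrt((centres[, 1] - cy)^2 + (centres[, 2] - cx)^2) >
                centres[, 3] + 2.2 * r + 3)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) next # crowded canvas: skip this weed rather than fail
      mem <- .blade(H, W, cy, cx, r)
      img <- .paint(img, mem, c(0.35, 0.58, 0.16), shade)
      mask[mem] <- 2L
    }

    if (spec$noise_level > 0) {
      img <- img + array(rnorm(H * W * 3, sd = spec$noise_level),
                         c(H, W, 3))
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = mask)
  })
}

#' Generate a split synthetic dataset
#'
#' Draws disjoint per-split seed streams (split first), generates the
#' scenes of each split independently, and only then optionally augments
#' within each split - never across splits, so no augmented copy of a
#' training scene can leak into validation or test.
#'
#' @param spec a [scene_spec()]; its `seed` field is ignored here.
#' @param n_train,n_val,n_test positive split sizes.
#' @param seed master seed for the split seed streams.
#' @param augment apply random flip/blur augmentation within each split?
#' @return `list(train =, val =, test =)`, each a list of
#'   `list(image =, mask =)` pairs; per-split seeds are attached as
#'   attribute `"split_seeds"`.
#' @export
generate_synthetic_dataset <- function(spec, n_train, n_val, n_test,
                                       seed = 1L, augment = FALSE) {
  stopifnot(inherits(spec, "ws_scene_spec"))
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop("generate_synthetic_dataset: split sizes must be positive")
  split_seeds <- with_seed(seed, sample.int(2^31 - 10^6, 3))
  gen_split <- function(split_seed, n) {
    lapply(seq_len(n), function(i) {
      sp <- spec
      sp$seed <- split_seed + i
      sc <- generate_synthetic_scene(sp)
      if (augment) sc <- augment(sc$image, sc$mask, seed = split_seed + i)
      sc
    })
  }
  out <- list(train = gen_split(split_seeds[1], n_train),
              val = gen_split(split_seeds[2], n_val),
              test = gen_split(split_seeds[3], n_test))
  attr(out, "split_seeds") <- split_seeds
  out
}
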