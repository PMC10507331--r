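# ---------------------------------------------------------------------------
# Synthetic blood-smear generator and dataset preprocessing.
#
# Emulates stained peripheral-blood smears: large near-circular leukocytes
# (dark lobed nucleus inside lighter cytoplasm), smaller pale erythrocyte
# annuli as unannotated distractors, optional touching/overlapping leukocyte
# pairs (adhesion), staining/illumination jitter and sensor noise.
# Annotations are per-leukocyte binary masks with tight boxes, serializable
# as COCO-style instance JSON (uncompressed column-major RLE).
# ---------------------------------------------------------------------------

#' Specification of one synthetic smear image
#'
#' @param width,height canvas size in pixels
#' @param n_wbc number of annotated leukocytes
#' @param n_rbc number of unannotated erythrocyte distractors
#' @param overlap_prob probability that a leukocyte pair is placed adhering
#'   (requires `n_wbc >= 2`)
#' @param min_overlap minimum mask intersection of an adhering pair, as a
#'   fraction of the smaller mask's area (in `[0, 1)`)
#' @param wbc_radius leukocyte radius range, fraction of the shorter side
#' @param rbc_radius erythrocyte radius range, fraction of the shorter side
#' @param noise_sd additive Gaussian noise level on [0,1] intensities
#' @param illum_strength amplitude of the smooth illumination gradient
#' @param color_jitter multiplicative staining-color jitter amplitude
#' @param seed RNG seed fixing the whole sample (NULL = use current RNG)
#' @return object of class `smear_spec`
#' @export
smear_spec <- function(width = 128L, height = width, n_wbc = 3L, n_rbc = 12L,
                       overlap_prob = 0.3, min_overlap = 0.2,
                       wbc_radius = c(0.10, 0.16),
                       rbc_radius = c(0.035, 0.055),
                       noise_sd = 0.02, illum_strength = 0.06,
                       color_jitter = 0.08, seed = NULL) {
  stopifnot(n_wbc >= 0, n_rbc >= 0, min_overlap >= 0, min_overlap < 1,
            width >= 32, height >= 32)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_wbc = as.integer(n_wbc), n_rbc = as.integer(n_rbc),
                 overlap_prob = overlap_prob, min_overlap = min_overlap,
                 wbc_radius = wbc_radius, rbc_radius = rbc_radius,
                 noise_sd = noise_sd, illum_strength = illum_strength,
                 color_jitter = color_jitter, seed = seed),
            class = "smear_spec")
}

# blobby cell mask: radial Fourier perturbation of a disc, on the full grid
blob_mask <- function(H, W, cx, cy, r0, wobble = 0.08, nharm = 3L) {
  amp <- stats::runif(nharm, 0, wobble)
  phase <- stats::runif(nharm, 0, 2 * pi)
  xs <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE) - cx
  ys <- matrix(seq_len(H) - 0.5, H, W) - cy
  theta <- atan2(ys, xs)
  rad <- r0 * (1 + Reduce(`+`, lapply(seq_len(nharm), function(k)
    amp[k] * cos((k + 1) * theta + phase[k]))))
  (sqrt(xs^2 + ys^2) < rad) * 1L
}

mask_overlap_frac <- function(a, b) {
  inter <- sum(a & b)
  inter / max(1, min(sum(a), sum(b)))
}

#' Tight bounding box of a mask
#'
#' @param mask 0/1 matrix
#' @return `c(x, y, w, h)`, 0-based pixel coordinates, half-open
#' @export
mask_to_bbox <- function(mask) {
  pos <- which(mask > 0, arr.ind = TRUE)
  if (!nrow(pos)) return(c(0, 0, 0, 0))
  x1 <- min(pos[, 2]); x2 <- max(pos[, 2])
  y1 <- min(pos[, 1]); y2 <- max(pos[, 1])
  c(x1 - 1, y1 - 1, x2 - x1 + 1, y2 - y1 + 1)
}

#' Generate one synthetic blood-smear image with instance annotations
#'
#' Deterministic under `spec$seed`. When adhesion is requested the generator
#' re-places the second cell of a pair until its mask intersects the first
#' by at least `min_overlap` of the smaller mask (bounded retries). Cell
#' placement errors out after bounded retries when the canvas cannot hold
#' the requested count.
#'
#' @param spec a [smear_spec()]
#' @return list with `image` (`H x W x 3` array in `[0,1]`) and
#'   `annotations` (list of `list(mask, bbox, area, category)`)
#' @export
generate_smear <- function(spec) {
  stopifnot(inherits(spec, "smear_spec"))
  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(spec$seed)
  }
  H <- spec$height; W <- spec$width
  side <- min(H, W)
  # background with smooth illumination gradient
  gx <- stats::runif(1, -1, 1); gy <- stats::runif(1, -1, 1)
  ill <- spec$illum_strength *
    (outer(seq_len(H) / H - 0.5, rep(1, W)) * gy +
       outer(rep(1, H), seq_len(W) / W - 0.5) * gx)
  base <- c(0.97, 0.94, 0.96) * stats::runif(3, 1 - spec$color_jitter / 2, 1)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- pmin(1, base[ch] + ill)

  jit <- function(col) pmin(1, pmax(0, col * stats::runif(3, 1 - spec$color_jitter,
                                                          1 + spec$color_jitter)))
  paint <- function(img, mask, col, blend = 1) {
    idx <- mask > 0
    for (ch in 1:3)
      img[, , ch][idx] <- (1 - blend) * img[, , ch][idx] + blend * col[ch]
    img
  }

  # erythrocytes: pale annuli, never annotated
  for (i in seq_len(spec$n_rbc)) {
    r <- stats::runif(1, spec$rbc_radius[1], spec$rbc_radius[2]) * side
    cx <- stats::runif(1, r, W - r); cy <- stats::runif(1, r, H - r)
    outer_m <- blob_mask(H, W, cx, cy, r, wobble = 0.04)
    inner_m <- blob_mask(H, W, cx, cy, r * 0.45, wobble = 0.04)
    col <- jit(c(0.92, 0.72, 0.72))
    img <- paint(img, outer_m & !inner_m, col, blend = 0.85)
    img <- paint(img, inner_m, pmin(1, col * 1.07), blend = 0.5)
  }

  # leukocytes
  anns <- list()
  masks <- list()
  place_budget <- 200L
  i <- 1L
  while (i <= spec$n_wbc) {
    r <- stats::runif(1, spec$wbc_radius[1], spec$wbc_radius[2]) * side
    adhere <- (i > 1L) && stats::runif(1) < spec$overlap_prob
    placed <- FALSE
    for (try in seq_len(place_budget)) {
      if (adhere) {
        j <- sample.int(i - 1L, 1L)
        prev <- attr(masks[[j]], "geom")
        d <- stats::runif(1, 0.55, 0.9) * (prev$r + r)
        ang <- stats::runif(1, 0, 2 * pi)
        cx <- prev$cx + d * cos(ang); cy <- prev$cy + d * sin(ang)
      } else {
        cx <- stats::runif(1, r + 1, W - r - 1)
        cy <- stats::runif(1, r + 1, H - r - 1)
      }
      if (cx < r * 0.5 || cx > W - r * 0.5 || cy < r * 0.5 || cy > H - r * 0.5)
        next
      m <- blob_mask(H, W, cx, cy, r)
      if (sum(m) < 9) next
      ok <- TRUE
      if (adhere) {
        if (mask_overlap_frac(m, masks[[j]]) < spec$min_overlap) ok <- FALSE
        # and stay clear of all other cells
        for (q in setdiff(seq_along(masks), j))
          if (mask_overlap_frac(m, masks[[q]]) > 0.05) ok <- FALSE
      } else {
        for (q in seq_along(masks))
          if (mask_overlap_frac(m, masks[[q]]) > 0.05) ok <- FALSE
      }
      if (!ok) next
      attr(m, "geom") <- list(cx = cx, cy = cy, r = r)
      masks[[i]] <- m
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place leukocyte ", i, " after ", place_budget,
           " attempts; canvas too crowded")
    i <- i + 1L
  }

  # draw cytoplasm then nuclei; adhesion regions darken slightly
  cyto_cols <- list(); nuc_cols <- list()
  for (i in seq_along(masks)) {
    cyto_cols[[i]] <- jit(c(0.72, 0.62, 0.85))
    nuc_cols[[i]] <- jit(c(0.32, 0.18, 0.45))
  }
  for (i in seq_along(masks))
    img <- paint(img, masks[[i]], cyto_cols[[i]], blend = 0.95)
  if (length(masks) >= 2) {
    for (i in 2:length(masks)) for (j in 1:(i - 1)) {
      inter <- masks[[i]] & masks[[j]]
      if (any(inter)) img <- paint(img, inter, c(0.55, 0.45, 0.70), blend = 0.8)
    }
  }
  for (i in seq_along(masks)) {
    g <- attr(masks[[i]], "geom")
    n_lobes <- sample(2:3, 1)
    for (l in seq_len(n_lobes)) {
      lr <- g$r * stats::runif(1, 0.3, 0.45)
      ang <- 2 * pi * l / n_lobes + stats::runif(1, -0.5, 0.5)
      off <- stats::runif(1, 0.15, 0.4) * g$r
      lm <- blob_mask(H, W, g$cx + off * cos(ang), g$cy + off * sin(ang), lr)
      img <- paint(img, lm & masks[[i]], nuc_cols[[i]], blend = 0.9)
    }
  }

  img <- img + array(stats::rnorm(H * W * 3, 0, spec$noise_sd), c(H, W, 3))
  img[img < 0] <- 0
  img[img > 1] <- 1

  for (i in seq_along(masks)) {
    m <- masks[[i]]; attr(m, "geom") <- NULL
    anns[[i]] <- list(mask = m, bbox = mask_to_bbox(m), area = sum(m),
                      category = "wbc")
  }
  list(image = img, annotations = anns)
}

# --- preprocessing ops -----------------------------------------------------

# window origins along one axis (0-based): the stride grid plus a final
# edge-anchored window when the stride does not tile exactly
window_origins <- function(size, window, stride) {
  if (size <= window) return(0L)
  org <- seq.int(0L, size - window, by = stride)
  if (org[length(org)] + window < size) org <- c(org, size - window)
  as.integer(org)
}

#' Sliding-window crop of an image (and its annotations)
#'
#' Cuts `window x window` tiles at the given stride, anchoring a final
#' right/bottom window to the image edge when the stride does not tile
#' exactly. Annotation masks are cropped with the tile; instances keeping at
#' least `keep_frac` of their area survive (with recomputed boxes), others
#' are dropped. An image smaller than the window yields a single zero-padded
#' tile with a warning.
#'
#' @param image `H x W x 3` array
#' @param annotations optional list of instance annotations (as produced by
#'   [generate_smear()])
#' @param window tile side (pixels)
#' @param stride step between tile origins (pixels)
#' @param keep_frac minimum surviving area fraction of a clipped instance
#' @return list of tiles: `list(image, offset = c(x0, y0), annotations)`
#'   with 0-based offsets
#' @export
sliding_window_crop <- function(image, annotations = NULL, window = 512L,
                                stride = 256L, keep_frac = 0.25) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H < window || W < window) {
    warning("image smaller than window; emitting one zero-padded tile")
    tile <- array(0, c(window, window, dim(image)[3]))
    tile[seq_len(min(H, window)), seq_len(min(W, window)), ] <-
      image[seq_len(min(H, window)), seq_len(min(W, window)), ]
    anns <- lapply(annotations, function(a) {
      m <- matrix(0L, window, window)
      m[seq_len(min(H, window)), seq_len(min(W, window))] <-
        a$mask[seq_len(min(H, window)), seq_len(min(W, window))]
      list(mask = m, bbox = mask_to_bbox(m), area = sum(m),
           category = a$category)
    })
    return(list(list(image = tile, offset = c(0L, 0L), annotations = anns)))
  }
  xs <- window_origins(W, window, stride)
  ys <- window_origins(H, window, stride)
  tiles <- list()
  for (y0 in ys) for (x0 in xs) {
    tile <- image[(y0 + 1):(y0 + window), (x0 + 1):(x0 + window), , drop = FALSE]
    anns <- list()
    for (a in annotations) {
      m <- a$mask[(y0 + 1):(y0 + window), (x0 + 1):(x0 + window), drop = FALSE]
      if (sum(m) >= keep_frac * a$area && sum(m) > 0)
        anns[[length(anns) + 1L]] <- list(mask = m, bbox = mask_to_bbox(m),
                                          area = sum(m), category = a$category)
    }
    tiles[[length(tiles) + 1L]] <-
      list(image = tile, offset = c(x0, y0), annotations = anns)
  }
  tiles
}

#' Zero-pad an image to a square
#'
#' Padding goes on the bottom/right, so annotation coordinates are unshifted.
#' @param image `H x W x C` array (or `H x W` matrix)
#' @return padded square array of side `max(H, W)`
#' @export
pad_to_square <- function(image) {
  d <- dim(image)
  s <- max(d[1], d[2])
  if (d[1] == d[2]) return(image)
  if (length(d) == 2L) {
    out <- matrix(0, s, s)
    out[seq_len(d[1]), seq_len(d[2])] <- image
  } else {
    out <- array(0, c(s, s, d[3]))
    out[seq_len(d[1]), seq_len(d[2]), ] <- image
  }
  out
}

#' Deterministic train/validation/test split
#'
#' Items are shuffled under the seed and split at the cumulative-floor
#' boundaries of the ratio vector, so sizes are `floor(n * cum(r)/sum(r))`
#' differences (678 items at 7:1:2 give 474/68/136).
#'
#' @param ids vector of item identifiers (or an integer count)
#' @param ratios positive split weights, e.g. `c(7, 1, 2)`
#' @param seed shuffle seed
#' @return named list `train`, `val`, `test` (or `split1..k` for other
#'   lengths); disjoint and exhaustive
#' @export
split_dataset <- function(ids, ratios = c(7, 1, 2), seed = 1L) {
  stopifnot(all(ratios > 0))
  if (length(ids) == 1L && is.numeric(ids) && ids == as.integer(ids) && ids > 1)
    ids <- seq_len(ids)
  n <- length(ids)
  if (n < length(ratios)) stop("fewer items than splits")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  perm <- sample(ids)
  bounds <- floor(n * cumsum(ratios) / sum(ratios))
  out <- list()
  start <- 1L
  for (i in seq_along(ratios)) {
    out[[i]] <- if (bounds[i] >= start) perm[start:bounds[i]] else ids[0]
    start <- bounds[i] + 1L
  }
  names(out) <- if (length(ratios) == 3L) c("train", "val", "test")
  else paste0("split", seq_along(ratios))
  out
}

# --- COCO-style serialization ----------------------------------------------

#' Uncompressed COCO RLE encoding of a binary mask
#'
#' Column-major run lengths, first count giving the number of leading zeros
#' (possibly 0).
#' @param mask 0/1 matrix
#' @return list with `counts` (integer vector) and `size` (`c(H, W)`)
#' @export
rle_encode <- function(mask) {
  v <- as.integer(as.vector(mask) > 0)
  r <- rle(v)
  counts <- r$lengths
  if (length(v) == 0L) counts <- integer(0)
  else if (r$values[1] == 1L) counts <- c(0L, counts)
  list(counts = as.integer(counts), size = dim(mask))
}

#' Decode an uncompressed COCO RLE into a binary mask
#'
#' @param rle list with `counts` and `size` as from [rle_encode()]
#' @return 0/1 integer matrix
#' @export
rle_decode <- function(rle) {
  h <- rle$size[1]; w <- rle$size[2]
  vals <- rep(rep(c(0L, 1L), length.out = length(rle$counts)), rle$counts)
  stopifnot(length(vals) == h * w)
  matrix(vals, h, w)
}

#' Convert generated smears into a COCO-style instance dataset
#'
#' @param smears list of outputs of [generate_smear()]
#' @param file_names optional per-image file names
#' @return list with `images`, `annotations`, `categories` following the
#'   COCO instance schema (RLE segmentations)
#' @export
as_coco <- function(smears, file_names = NULL) {
  images <- list(); annotations <- list()
  aid <- 1L
  for (i in seq_along(smears)) {
    img <- smears[[i]]$image
    images[[i]] <- list(
      id = i,
      file_name = if (is.null(file_names)) sprintf("img_%04d.png", i)
      else file_names[i],
      height = dim(img)[1], width = dim(img)[2])
    for (a in smears[[i]]$annotations) {
      annotations[[aid]] <- list(
        id = aid, image_id = i, category_id = 1L,
        segmentation = rle_encode(a$mask),
        area = a$area, bbox = a$bbox, iscrowd = 0L)
      aid <- aid + 1L
    }
  }
  list(images = images, annotations = annotations,
       categories = list(list(id = 1L, name = "wbc")))
}

#' Write a COCO-style dataset to JSON
#'
#' @param coco list from [as_coco()]
#' @param path output JSON path
#' @export
write_coco <- function(coco, path) {
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO-style dataset from JSON
#'
#' @param path JSON path
#' @return list with `images`, `annotations`, `categories`;
#'   RLE `counts` restored as integer vectors
#' @export
read_coco <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$annotations <- lapply(x$annotations, function(a) {
    a$segmentation$counts <- as.integer(unlist(a$segmentation$counts))
    a$segmentation$size <- as.integer(unlist(a$segmentation$size))
    a$bbox <- as.numeric(unlist(a$bbox))
    a
  })
  x
}

#' Generate a ready synthetic dataset
#'
#' @param n number of images
#' @param spec template [smear_spec()]; each image uses `seed + i`
#' @param seed base seed
#' @param dir optional output directory: PNG images plus
#'   `annotations.json` are written there
#' @return list of smears (`image` + `annotations`) with the COCO table as
#'   attribute `coco`
#' @export
synth_dataset <- function(n, spec = smear_spec(), seed = 1L, dir = NULL) {
  smears <- lapply(seq_len(n), function(i) {
    s <- spec; s$seed <- seed + i
    generate_smear(s)
  })
  coco <- as_coco(smears)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(smears))
      EBImage::writeImage(
        EBImage::Image(aperm(smears[[i]]$image, c(2, 1, 3)),
                       colormode = "Color"),
        file.path(dir, coco$images[[i]]$file_name))
    write_coco(coco, file.path(dir, "annotations.json"))
  }
  attr(smears, "coco") <- coco
  smears
}
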