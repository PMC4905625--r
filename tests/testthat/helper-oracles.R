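# Independent oracles and small fixture builders used across the suite.

# Brute-force 8-connected component counter: queue-based flood fill over
# the mask, written without any labelling library so it can serve as an
# independent oracle for count_objects()/label_components().
flood_fill_count <- function(mask, min_area = 1, max_area = Inf) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  stack <- integer(sum(mask))  # linear indices, preallocated
  sizes <- integer()
  for (start in which(mask)) {
    if (seen[start]) next
    seen[start] <- TRUE
    stack[1] <- start
    top <- 1L
    size <- 0L
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      size <- size + 1L
      i <- ((p - 1L) %% nr) + 1L
      j <- ((p - 1L) %/% nr) + 1L
      for (di in -1:1) for (dj in -1:1) {
        ni <- i + di; nj <- j + dj
        if (ni >= 1L && ni <= nr && nj >= 1L && nj <= nc) {
          q <- (nj - 1L) * nr + ni
          if (mask[q] && !seen[q]) {
            seen[q] <- TRUE
            top <- top + 1L
            stack[top] <- q
          }
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sum(sizes >= min_area & sizes <= max_area)
}

# uniform-colour test image (H x W x 3, 0-255)
flat_image <- function(h, w, rgb) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# tissue-only phantom spec (no stain) of side `px`
blank_tissue_spec <- function(px = 96L)
  phantom_spec(px, px, tissue_fraction = 0.9)

# phantom with a single object group, for counting tests
object_phantom <- function(marker, n, area_range, darkness = 60L,
                           px = 192L, seed = 1, ...) {
  sp <- phantom_spec(px, px,
                     objects = list(list(marker = marker, n_objects = n,
                                         area_px_range = area_range,
                                         chromogen_darkness = darkness)),
                     ...)
  render_slide_phantom(sp, seed)
}
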