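# Shared small fixtures and independent oracles.
#
# The "small" beam/field is deliberately coarse (4 layers, 2 mm grid, ~60 CTV
# voxels) so accumulation tests run in milliseconds; short SOBPs cannot reach
# the 2% flatness of the 14-layer reference field, hence the looser tolerance
# here.

small_beam <- function() {
  model <- bragg_peak(10, 0.6)
  layers <- solve_layer_weights(model, build_layer_set(10, 2.4, 0.6),
                                flatness_tol = 0.1)
  list(model = model, layers = layers)
}

small_field <- function(beam = small_beam(), beam_axis = "-x",
                        voxel_mm = 3, normalize = "ctv_min") {
  ctv <- ctv_geometry(c(8, 7, 7.5), voxel_mm = voxel_mm)
  field <- build_field(beam$model, beam$layers, field_geometry(beam_axis),
                       ctv, grid_spacing_mm = 2, pad_mm = 18,
                       normalize = normalize)
  list(model = beam$model, layers = beam$layers, ctv = ctv, field = field)
}

# constant-displacement 1 Hz trace covering n_sec seconds
const_trace <- function(offset_lr_si_ap, n_sec) {
  motion_trace(0:n_sec, matrix(rep(offset_lr_si_ap, each = n_sec + 1),
                               n_sec + 1, 3), 1)
}

# independent trilinear interpolation: scalar, loop-based
naive_trilinear <- function(g, p) {
  ax <- lapply(1:3, function(i)
    g$origin_mm[i] + (seq_len(dim(g$values)[i]) - 1) * g$spacing_mm[i])
  f <- numeric(3); i0 <- integer(3)
  for (i in 1:3) {
    fi <- (p[i] - g$origin_mm[i]) / g$spacing_mm[i]
    i0[i] <- min(max(floor(fi), 0), dim(g$values)[i] - 2)
    f[i] <- fi - i0[i]
  }
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) f[1] else 1 - f[1]) *
           (if (dy) f[2] else 1 - f[2]) *
           (if (dz) f[3] else 1 - f[3])
    acc <- acc + wgt * g$values[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  acc
}

# brute-force fraction accumulation: loops over (second, segment, voxel) with
# no vectorization, independent of accumulate_fraction internals
naive_accumulate <- function(field, timeline, trace, ctv = field$ctv) {
  n_sec <- ceiling(attr(timeline, "end_s") - 1e-9)
  vox <- ctv$voxels_mm
  dose <- numeric(nrow(vox))
  for (t in seq_len(n_sec) - 1L) {
    d <- trace$disp_mm[which(trace$times_s == t), ]
    for (s in seq_len(nrow(timeline))) {
      if (timeline$dose_frac[s] == 0) next
      ov <- min(timeline$end_s[s], t + 1) - max(timeline$start_s[s], t)
      if (ov <= 0) next
      dur <- timeline$end_s[s] - timeline$start_s[s]
      for (v in seq_len(nrow(vox))) {
        p <- c(vox[v, 1] + d[1], vox[v, 2] + d[3], vox[v, 3] + d[2])
        if (timeline$source[s] == "full_beam") {
          dose[v] <- dose[v] + ov / dur * naive_trilinear(field$composed, p)
        } else {
          k <- timeline$layer[s]
          dose[v] <- dose[v] + ov / dur * field$layer_scale[k] *
            naive_trilinear(field$layer_grids[[k]], p)
        }
      }
    }
  }
  dose
}
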