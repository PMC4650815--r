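# Shared fixture builders: everything is generated in code at test time.

# a rasterized straight tube and its spec, radius in um
tube_fixture <- function(radius_um = 95, length_mm = 2, voxel_um = 19,
                         start = c(0.3, 0.3, 0.3), direction = c(0, 1, 0),
                         supersample = 3) {
  direction <- direction / sqrt(sum(direction^2))
  tube <- make_tube(start, start + direction * length_mm, radius_um,
                    label = "tube")
  spec <- phantom_spec(list(tube), voxel_um = voxel_um)
  c(rasterize(spec, supersample), list(spec = spec, tube = tube))
}

# noiseless HU volume from a mask (vessel contrast on flat background)
mask_to_volume <- function(mask, vessel = 500, background = 73) {
  ct_volume(array(as.numeric(mask$data) * (vessel - background) + background,
                  dim(mask$data)),
            mask$voxel_um, mask$origin_mm)
}

# hand-drawn one-voxel-thick Y skeleton (three straight arms from a center)
y_skeleton <- function(voxel_um = 19) {
  a <- array(FALSE, c(21, 21, 5))
  a[1:10, 11, 3] <- TRUE           # west arm ending at center (10, 11)
  for (k in 1:8) a[10 + k, 11 + k, 3] <- TRUE  # NE arm
  for (k in 1:8) a[10 + k, 11 - k, 3] <- TRUE  # SE arm
  ct_volume(a, voxel_um)
}

# one-voxel-thick straight chain of n voxels
chain_skeleton <- function(n = 10, voxel_um = 19) {
  a <- array(FALSE, c(n + 4, 5, 5))
  a[3:(n + 2), 3, 3] <- TRUE
  ct_volume(a, voxel_um)
}

default_scales <- function() 15 * (10^(1 / 5))^(0:5)
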