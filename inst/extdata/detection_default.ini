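# Default detection thresholds. All values are documented heuristics meant
# to be tuned to the staining at hand.

[ihc]
# HSV box for the earthy red-brown of a DAB chromogen.
# Hue in degrees [0, 360); hue_lower > hue_upper means the interval wraps
# through 0. Saturation and value in [0, 1].
hue_lower = 0
hue_upper = 50
sat_lower = 0.2
sat_upper = 1
val_lower = 0.1
val_upper = 0.95
# Minimum connected-component size kept, in pixels; 0 disables the filter.
min_blob_size = 0

[if]
# Intensity threshold in [0, 1], or "otsu" for a per-image automatic level.
threshold = otsu
min_blob_size = 0
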