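# Single-layer CLB, anisotropically oriented clusters (one preferred
# direction per cluster with angular jitter).  Placeholder defaults.
name=simpori
image_size=256
gray_offset=0
gray_scale=48
gray_clip=0,255
layers=1
layer1.mean_cluster_count=80
layer1.mean_blobs_per_cluster=15
layer1.cluster_spread=15
layer1.blob_length_x=8
layer1.blob_length_y=4
layer1.blob_alpha=2.1
layer1.blob_beta=0.5
layer1.orientation_mode=oriented
layer1.orientation_jitter=0.3
layer1.n_orientations=16
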