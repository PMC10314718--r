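# Original clustered lumpy background parameterization (single layer,
# isotropic blob orientations).  Editable defaults.
name=opex99
image_size=256
gray_offset=0
gray_scale=52
gray_clip=0,255
layers=1
layer1.mean_cluster_count=150
layer1.mean_blobs_per_cluster=20
layer1.cluster_spread=12
layer1.blob_length_x=5
layer1.blob_length_y=2
layer1.blob_alpha=2.1
layer1.blob_beta=0.5
layer1.orientation_mode=isotropic
layer1.orientation_jitter=0
layer1.n_orientations=16
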