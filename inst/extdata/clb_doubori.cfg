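# Double-layer CLB, anisotropically oriented clusters.  Placeholder
# defaults.
name=doubori
image_size=256
gray_offset=0
gray_scale=36
gray_clip=0,255
layers=2
layer1.mean_cluster_count=60
layer1.mean_blobs_per_cluster=15
layer1.cluster_spread=18
layer1.blob_length_x=10
layer1.blob_length_y=5
layer1.blob_alpha=2.1
layer1.blob_beta=0.5
layer1.orientation_mode=oriented
layer1.orientation_jitter=0.3
layer1.n_orientations=16
layer2.mean_cluster_count=150
layer2.mean_blobs_per_cluster=20
layer2.cluster_spread=10
layer2.blob_length_x=4
layer2.blob_length_y=2
layer2.blob_alpha=2.1
layer2.blob_beta=0.5
layer2.orientation_mode=oriented
layer2.orientation_jitter=0.3
layer2.n_orientations=16
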