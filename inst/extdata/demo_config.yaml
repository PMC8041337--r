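# Demo configuration for run_pipeline(): small synthetic cohort that
# completes end-to-end on one CPU in a few minutes.
output_dir: sfcoupling_demo_out
seed: 42
n_subjects: 5
n_hemispheres: 2
duration_s: 60        # seconds of recording per observation
fs: 300               # Hz
sensor_snr: 1
n_sensors: 24
grid_spacing: 5       # mm source grid
voxel_size: 2         # mm output image resolution
brain_radius: 28      # mm toy brain sphere
regularization: 0.05  # fraction of mean sensor power
forming_p: 0.01       # cluster-forming threshold (upper-tail p)
n_perm: 500           # cluster permutations
seed_radius: 3        # mm streamline seed sphere
band: low_beta        # delta_theta | low_beta | high_beta
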