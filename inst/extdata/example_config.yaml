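# Reference scenario of the evaluation pipeline (see ?pipeline_config).
seed: 1
n_frames: 300          # sentence length T
n_experiments: 20      # test sentences S
n_train_experiments: 5 # training sentences P
train_frames_per_class: 7   # K
frames_per_class: 30        # pool size N
mixture_components: 1       # M
selection_method: sffs
subset_size: 17
garbage_ratio: 0.3333333333333333
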