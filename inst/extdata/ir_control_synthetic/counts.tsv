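feature_id	ctrl_1	ctrl_2	ctrl_3	ctrl_4	ctrl_5	ctrl_6
ctrlG	1000	1000	1000	1000	1000	1000
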