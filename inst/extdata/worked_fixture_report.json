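{"estimates":{"v0":79.9689319767,"kb":0.5219936971,"kd0":1.5374857376,"w0":59.9013501579},"feedback":{"slope":-0.02566696299,"intercept":1.5374857376,"stderr_slope":0.00028617309959,"stderr_intercept":0.0062158289867,"r2":0.87511364513,"n":1150,"w0_valid":true,"ci_kd0":[1.5259146337,1.5506240668],"ci_w0":[58.9427090121,60.7986506014]},"branching":{"rate":0.5219936971,"log_intercept":-0.17240849433,"ci95_rate":[0.48474276069,0.5592446335],"rate_fixed_intercept":0.49477130325,"r2":0.99366484048,"n":9},"tip_speed":{"v0_hat":79.9689319767,"sd":6.9756382946,"n_tracks":374},"seed":42,"package_version":"0.1.0"}
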