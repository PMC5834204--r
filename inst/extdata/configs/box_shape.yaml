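# skittler task configuration
# units: lengths cm, times s, omega rad/s, sample_rate Hz
# tau: .inf means an undamped (tau = infinity) flight
post_center:
- 0.0
- 0.0
post_radius: 25.0
target_center:
- 25.0
- 45.0
target_radius: 2.5
ball_radius: 2.5
lever_pivot:
- 0.0
- -150.0
lever_length: 40.0
omega: 6.283185307179586
tau: 10.0
success_threshold: 1.1
miss_threshold: 2.5
max_display_error: 40.0
throw_direction: clockwise
sample_rate: 1000.0
name: box_shape

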