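plan,measured,calculated
overlay_and_coils,206.06,206.8
no_coils_only_overlay,206.06,208.3
no_overlay_only_coils,206.06,209.2
no_overlay_or_coils,206.06,210.4
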