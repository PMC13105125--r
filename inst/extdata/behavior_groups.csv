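raw_label,group_label
sleep,sleep
awaken,sleep
twitch,twitch
eat zone 1,eat
eat zone 2,eat
chew,eat
drink zone 1,drink
drink zone 2,drink
groom,groom
groom back,groom
groom front,groom
scratch,groom
walk left,walk
walk right,walk
walk slowly,walk
turn left,turn
turn right,turn
circle,turn
rear up,rear
rear up partial,rear
come down,rear
hang cuddled,hang
hang vertically,hang
sniff,sniff
sniff up,sniff
dig,dig
forage,forage
jump,jump
land vertically,jump
stretch body,stretch
pause,pause
remain low,pause
stationary,pause
unknown behavior,Other
eat,eat
drink,drink
turn,turn
rear,rear
hang,hang
jump,jump
stretch,stretch
walk,walk
Other,Other
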