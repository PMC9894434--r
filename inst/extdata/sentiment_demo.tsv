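dobry	positive
miły	positive
piękny	positive
wspaniały	positive
radosny	positive
szczęśliwy	positive
udany	positive
cenny	positive
mądry	positive
pogodny	positive
zły	negative
brzydki	negative
smutny	negative
okropny	negative
przykry	negative
nudny	negative
słaby	negative
groźny	negative
podły	negative
ponury	negative
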