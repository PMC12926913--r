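>consensus
GNLVHTHSIVMASLYEQTPDDLHVVKTPSDEKAVAPHCESEVHFFTNITENLAIECLNAGDHFSSHVGAIAAPKALANMD
MTAWLEGIAVPEKLHLCAMI
>var1
GNLGHTHSIVMASLEYQTPGDVHVVKTPSDEKAVAPHCESEVHFFTNITENLARECLNAGDHFSSHVGSIAAPKALANMD
MTAWLEGIAVPEKLHLCAMI
>var2
GNLVHTHSIVMASLYEQPPDDLHVVKTASDEKAVAPPCESEVHFFTNITENLAIECLNAGDHFSSHVGAIAAPKALANMD
MTAWLEGIAVPEKLHLCAMI
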