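>G1_anchor1
GWLVTKLPSVVTRTAPVVFREIGISNACRLQAKIDHDVDVLIYRNVYGLIEDVKFWCNFCVDDGRSDAKKQRDEYQERAW
SALGLAGMDTMESYRDRRQHDTGANICKYSLTAIKEEEFKKWTQQITEESDYMTQGPEVEKFLGSPEGKYDFYETAMTTS
NGDEVYANEQGEVKRLRFCIYDVHPCQRHGRNGARRVPHMGVSDLCLFTVIYFQQWQYKQIARIPLDHAPGVGPIIAHDI
KAGGVCICSMKYVFVAVLIDLVTTGLDSRVLGMVHRKDVDEMVRATVDDDLDENSVPPQQFDSTLQYTYKEEREREKTDG
SVCDIIERKICEGEKRLFALTDRGKVPLGSVAKAVGIPSFSVADKFENGW
>G1_anchor2
GWLVTKLPSVVTRTAPVVFREIGISTACRLKAKIDHDVDDLIYRNVYGLIEDVKFWCNFCVDDGRSDAKKQRDWYQERAW
SALGLAGMDTMESYRDREQHDTGANICKYSLTAIKEEIFKKWTQQIFEESDYMTQGPEVEKFLGSPEGKYDFYHTAMTTS
NGDEVYANEQGEVKRLRFCIYDVHPCQNHGRNGARRGPHMGVSDLCLFQVIYFQQWQYKQIARIPLDHAEGVGPIIAHDI
KAGGVCICSMKYVFVAVLIDLVITSLDSRVLGMVHRKDVDEMVRATVDDDLDENSVPPVQFDSLLQYTYKEEREREKTDG
SVCDPIEMKICEGEKRLFALTDRGKVPLGSVAKAVGIPSFSVADKFENGW
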