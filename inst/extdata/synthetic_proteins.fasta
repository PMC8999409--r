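>TM9S3 synthetic carrier of documented glycopeptide(s)
MAGLLKIVDVNLTSEGKAAGELVDPLWEKLGQEVPK
>TFR1 synthetic carrier of documented glycopeptide(s)
MVELDKDFEDLYTPVNGSIVIVRAGEITFAEKLAGTESPVREEPGEDFPAARLVWADLE
>GLPA synthetic carrier of documented glycopeptide(s)
MYGKDTYAATPRAHEVSEISVRTVYPPEEETGERVQLAHHFSEPEITLIIFGVMAGVIGTILLISYGIRR
>B3AT synthetic carrier of documented glycopeptide(s)
MEELQDDYEDKLSVPDGFKVSNSSARGWVIHPLGLR
>FAM3C synthetic carrier of documented glycopeptide(s)
MLRSALDTAARSTKPPRYLVGQEVTPEVLAK
>GPC4 synthetic carrier of documented glycopeptide(s)
MNVLAKFRPHHPEERPTTAAGTSLDRLVTEAGK
>LAMP1 synthetic carrier of documented glycopeptide(s)
MAAPGKGHTLTLNFTRNATHDLVAEVGK
>CD63 synthetic carrier of documented glycopeptide(s)
MAVEGKNNHTASILDRLEVELGNAVAK
>CD276 synthetic carrier of documented glycopeptide(s)
MLGVKTALFPDLLAQGNASLRLQDAGVYR
>S29A1 synthetic carrier of documented glycopeptide(s)
MTTSHQPQDRDAQASAAPAAPLPERVQLLEK
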